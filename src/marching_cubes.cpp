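// Marching cubes over a 3-D scalar grid (classic 256-case triangulation).
//
// Corner numbering within a cell (offsets along array dims d1,d2,d3):
//   0:(0,0,0) 1:(1,0,0) 2:(1,1,0) 3:(0,1,0) 4:(0,0,1) 5:(1,0,1) 6:(1,1,1) 7:(0,1,1)
// Edge numbering: 0..3 bottom ring, 4..7 top ring, 8..11 verticals.
// The case index sets bit c when the corner value is BELOW the iso level;
// with the canonical table this yields triangles wound so that
// cross(v1-v0, v2-v0) points away from the above-iso (inside) region.
// Vertices are shared through a global edge key, so the mesh is indexed
// (welded), which is what the watertightness checks rely on.

#include <Rcpp.h>
#include <unordered_map>
#include <vector>
using namespace Rcpp;

static const signed char TRI_TABLE[256][16] = {
 {-1,-1,-1,-1,-1,-1,-1,-1,-1,-1,-1,-1,-1,-1,-1,-1},
 {0,8,3,-1,-1,-1,-1,-1,-1,-1,-1,-1,-1,-1,-1,-1},
 {0,1,9,-1,-1,-1,-1,-1,-1,-1,-1,-1,-1,-1,-1,-1},
 {1,8,3,9,8,1,-1,-1,-1,-1,-1,-1,-1,-1,-1,-1},
 {1,2,10,-1,-1,-1,-1,-1,-1,-1,-1,-1,-1,-1,-1,-1},
 {0,8,3,1,2,10,-1,-1,-1,-1,-1,-1,-1,-1,-1,-1},
 {9,2,10,0,2,9,-1,-1,-1,-1,-1,-1,-1,-1,-1,-1},
 {2,8,3,2,10,8,10,9,8,-1,-1,-1,-1,-1,-1,-1},
 {3,11,2,-1,-1,-1,-1,-1,-1,-1,-1,-1,-1,-1,-1,-1},
 {0,11,2,8,11,0,-1,-1,-1,-1,-1,-1,-1,-1,-1,-1},
 {1,9,0,2,3,11,-1,-1,-1,-1,-1,-1,-1,-1,-1,-1},
 {1,11,2,1,9,11,9,8,11,-1,-1,-1,-1,-1,-1,-1},
 {3,10,1,11,10,3,-1,-1,-1,-1,-1,-1,-1,-1,-1,-1},
 {0,10,1,0,8,10,8,11,10,-1,-1,-1,-1,-1,-1,-1},
 {3,9,0,3,11,9,11,10,9,-1,-1,-1,-1,-1,-1,-1},
 {9,8,10,10,8,11,-1,-1,-1,-1,-1,-1,-1,-1,-1,-1},
 {4,7,8,-1,-1,-1,-1,-1,-1,-1,-1,-1,-1,-1,-1,-1},
 {4,3,0,7,3,4,-1,-1,-1,-1,-1,-1,-1,-1,-1,-1},
 {0,1,9,8,4,7,-1,-1,-1,-1,-1,-1,-1,-1,-1,-1},
 {4,1,9,4,7,1,7,3,1,-1,-1,-1,-1,-1,-1,-1},
 {1,2,10,8,4,7,-1,-1,-1,-1,-1,-1,-1,-1,-1,-1},
 {3,4,7,3,0,4,1,2,10,-1,-1,-1,-1,-1,-1,-1},
 {9,2,10,9,0,2,8,4,7,-1,-1,-1,-1,-1,-1,-1},
 {2,10,9,2,9,7,2,7,3,7,9,4,-1,-1,-1,-1},
 {8,4,7,3,11,2,-1,-1,-1,-1,-1,-1,-1,-1,-1,-1},
 {11,4,7,11,2,4,2,0,4,-1,-1,-1,-1,-1,-1,-1},
 {9,0,1,8,4,7,2,3,11,-1,-1,-1,-1,-1,-1,-1},
 {4,7,11,9,4,11,9,11,2,9,2,1,-1,-1,-1,-1},
 {3,10,1,3,11,10,7,8,4,-1,-1,-1,-1,-1,-1,-1},
 {1,11,10,1,4,11,1,0,4,7,11,4,-1,-1,-1,-1},
 {4,7,8,9,0,11,9,11,10,11,0,3,-1,-1,-1,-1},
 {4,7,11,4,11,9,9,11,10,-1,-1,-1,-1,-1,-1,-1},
 {9,5,4,-1,-1,-1,-1,-1,-1,-1,-1,-1,-1,-1,-1,-1},
 {9,5,4,0,8,3,-1,-1,-1,-1,-1,-1,-1,-1,-1,-1},
 {0,5,4,1,5,0,-1,-1,-1,-1,-1,-1,-1,-1,-1,-1},
 {8,5,4,8,3,5,3,1,5,-1,-1,-1,-1,-1,-1,-1},
 {1,2,10,9,5,4,-1,-1,-1,-1,-1,-1,-1,-1,-1,-1},
 {3,0,8,1,2,10,4,9,5,-1,-1,-1,-1,-1,-1,-1},
 {5,2,10,5,4,2,4,0,2,-1,-1,-1,-1,-1,-1,-1},
 {2,10,5,3,2,5,3,5,4,3,4,8,-1,-1,-1,-1},
 {9,5,4,2,3,11,-1,-1,-1,-1,-1,-1,-1,-1,-1,-1},
 {0,11,2,0,8,11,4,9,5,-1,-1,-1,-1,-1,-1,-1},
 {0,5,4,0,1,5,2,3,11,-1,-1,-1,-1,-1,-1,-1},
 {2,1,5,2,5,8,2,8,11,4,8,5,-1,-1,-1,-1},
 {10,3,11,10,1,3,9,5,4,-1,-1,-1,-1,-1,-1,-1},
 {4,9,5,0,8,1,8,10,1,8,11,10,-1,-1,-1,-1},
 {5,4,0,5,0,11,5,11,10,11,0,3,-1,-1,-1,-1},
 {5,4,8,5,8,10,10,8,11,-1,-1,-1,-1,-1,-1,-1},
 {9,7,8,5,7,9,-1,-1,-1,-1,-1,-1,-1,-1,-1,-1},
 {9,3,0,9,5,3,5,7,3,-1,-1,-1,-1,-1,-1,-1},
 {0,7,8,0,1,7,1,5,7,-1,-1,-1,-1,-1,-1,-1},
 {1,5,3,3,5,7,-1,-1,-1,-1,-1,-1,-1,-1,-1,-1},
 {9,7,8,9,5,7,10,1,2,-1,-1,-1,-1,-1,-1,-1},
 {10,1,2,9,5,0,5,3,0,5,7,3,-1,-1,-1,-1},
 {8,0,2,8,2,5,8,5,7,10,5,2,-1,-1,-1,-1},
 {2,10,5,2,5,3,3,5,7,-1,-1,-1,-1,-1,-1,-1},
 {7,9,5,7,8,9,3,11,2,-1,-1,-1,-1,-1,-1,-1},
 {9,5,7,9,7,2,9,2,0,2,7,11,-1,-1,-1,-1},
 {2,3,11,0,1,8,1,7,8,1,5,7,-1,-1,-1,-1},
 {11,2,1,11,1,7,7,1,5,-1,-1,-1,-1,-1,-1,-1},
 {9,5,8,8,5,7,10,1,3,10,3,11,-1,-1,-1,-1},
 {5,7,0,5,0,9,7,11,0,1,0,10,11,10,0,-1},
 {11,10,0,11,0,3,10,5,0,8,0,7,5,7,0,-1},
 {11,10,5,7,11,5,-1,-1,-1,-1,-1,-1,-1,-1,-1,-1},
 {10,6,5,-1,-1,-1,-1,-1,-1,-1,-1,-1,-1,-1,-1,-1},
 {0,8,3,5,10,6,-1,-1,-1,-1,-1,-1,-1,-1,-1,-1},
 {9,0,1,5,10,6,-1,-1,-1,-1,-1,-1,-1,-1,-1,-1},
 {1,8,3,1,9,8,5,10,6,-1,-1,-1,-1,-1,-1,-1},
 {1,6,5,2,6,1,-1,-1,-1,-1,-1,-1,-1,-1,-1,-1},
 {1,6,5,1,2,6,3,0,8,-1,-1,-1,-1,-1,-1,-1},
 {9,6,5,9,0,6,0,2,6,-1,-1,-1,-1,-1,-1,-1},
 {5,9,8,5,8,2,5,2,6,3,2,8,-1,-1,-1,-1},
 {2,3,11,10,6,5,-1,-1,-1,-1,-1,-1,-1,-1,-1,-1},
 {11,0,8,11,2,0,10,6,5,-1,-1,-1,-1,-1,-1,-1},
 {0,1,9,2,3,11,5,10,6,-1,-1,-1,-1,-1,-1,-1},
 {5,10,6,1,9,2,9,11,2,9,8,11,-1,-1,-1,-1},
 {6,3,11,6,5,3,5,1,3,-1,-1,-1,-1,-1,-1,-1},
 {0,8,11,0,11,5,0,5,1,5,11,6,-1,-1,-1,-1},
 {3,11,6,0,3,6,0,6,5,0,5,9,-1,-1,-1,-1},
 {6,5,9,6,9,11,11,9,8,-1,-1,-1,-1,-1,-1,-1},
 {5,10,6,4,7,8,-1,-1,-1,-1,-1,-1,-1,-1,-1,-1},
 {4,3,0,4,7,3,6,5,10,-1,-1,-1,-1,-1,-1,-1},
 {1,9,0,5,10,6,8,4,7,-1,-1,-1,-1,-1,-1,-1},
 {10,6,5,1,9,7,1,7,3,7,9,4,-1,-1,-1,-1},
 {6,1,2,6,5,1,4,7,8,-1,-1,-1,-1,-1,-1,-1},
 {1,2,5,5,2,6,3,0,4,3,4,7,-1,-1,-1,-1},
 {8,4,7,9,0,5,0,6,5,0,2,6,-1,-1,-1,-1},
 {7,3,9,7,9,4,3,2,9,5,9,6,2,6,9,-1},
 {3,11,2,7,8,4,10,6,5,-1,-1,-1,-1,-1,-1,-1},
 {5,10,6,4,7,2,4,2,0,2,7,11,-1,-1,-1,-1},
 {0,1,9,4,7,8,2,3,11,5,10,6,-1,-1,-1,-1},
 {9,2,1,9,11,2,9,4,11,7,11,4,5,10,6,-1},
 {8,4,7,3,11,5,3,5,1,5,11,6,-1,-1,-1,-1},
 {5,1,11,5,11,6,1,0,11,7,11,4,0,4,11,-1},
 {0,5,9,0,6,5,0,3,6,11,6,3,8,4,7,-1},
 {6,5,9,6,9,11,4,7,9,7,11,9,-1,-1,-1,-1},
 {10,4,9,6,4,10,-1,-1,-1,-1,-1,-1,-1,-1,-1,-1},
 {4,10,6,4,9,10,0,8,3,-1,-1,-1,-1,-1,-1,-1},
 {10,0,1,10,6,0,6,4,0,-1,-1,-1,-1,-1,-1,-1},
 {8,3,1,8,1,6,8,6,4,6,1,10,-1,-1,-1,-1},
 {1,4,9,1,2,4,2,6,4,-1,-1,-1,-1,-1,-1,-1},
 {3,0,8,1,2,9,2,4,9,2,6,4,-1,-1,-1,-1},
 {0,2,4,4,2,6,-1,-1,-1,-1,-1,-1,-1,-1,-1,-1},
 {8,3,2,8,2,4,4,2,6,-1,-1,-1,-1,-1,-1,-1},
 {10,4,9,10,6,4,11,2,3,-1,-1,-1,-1,-1,-1,-1},
 {0,8,2,2,8,11,4,9,10,4,10,6,-1,-1,-1,-1},
 {3,11,2,0,1,6,0,6,4,6,1,10,-1,-1,-1,-1},
 {6,4,1,6,1,10,4,8,1,2,1,11,8,11,1,-1},
 {9,6,4,9,3,6,9,1,3,11,6,3,-1,-1,-1,-1},
 {8,11,1,8,1,0,11,6,1,9,1,4,6,4,1,-1},
 {3,11,6,3,6,0,0,6,4,-1,-1,-1,-1,-1,-1,-1},
 {6,4,8,11,6,8,-1,-1,-1,-1,-1,-1,-1,-1,-1,-1},
 {7,10,6,7,8,10,8,9,10,-1,-1,-1,-1,-1,-1,-1},
 {0,7,3,0,10,7,0,9,10,6,7,10,-1,-1,-1,-1},
 {10,6,7,1,10,7,1,7,8,1,8,0,-1,-1,-1,-1},
 {10,6,7,10,7,1,1,7,3,-1,-1,-1,-1,-1,-1,-1},
 {1,2,6,1,6,8,1,8,9,8,6,7,-1,-1,-1,-1},
 {2,6,9,2,9,1,6,7,9,0,9,3,7,3,9,-1},
 {7,8,0,7,0,6,6,0,2,-1,-1,-1,-1,-1,-1,-1},
 {7,3,2,6,7,2,-1,-1,-1,-1,-1,-1,-1,-1,-1,-1},
 {2,3,11,10,6,8,10,8,9,8,6,7,-1,-1,-1,-1},
 {2,0,7,2,7,11,0,9,7,6,7,10,9,10,7,-1},
 {1,8,0,1,7,8,1,10,7,6,7,10,2,3,11,-1},
 {11,2,1,11,1,7,10,6,1,6,7,1,-1,-1,-1,-1},
 {8,9,6,8,6,7,9,1,6,11,6,3,1,3,6,-1},
 {0,9,1,11,6,7,-1,-1,-1,-1,-1,-1,-1,-1,-1,-1},
 {7,8,0,7,0,6,3,11,0,11,6,0,-1,-1,-1,-1},
 {7,11,6,-1,-1,-1,-1,-1,-1,-1,-1,-1,-1,-1,-1,-1},
 {7,6,11,-1,-1,-1,-1,-1,-1,-1,-1,-1,-1,-1,-1,-1},
 {3,0,8,11,7,6,-1,-1,-1,-1,-1,-1,-1,-1,-1,-1},
 {0,1,9,11,7,6,-1,-1,-1,-1,-1,-1,-1,-1,-1,-1},
 {8,1,9,8,3,1,11,7,6,-1,-1,-1,-1,-1,-1,-1},
 {10,1,2,6,11,7,-1,-1,-1,-1,-1,-1,-1,-1,-1,-1},
 {1,2,10,3,0,8,6,11,7,-1,-1,-1,-1,-1,-1,-1},
 {2,9,0,2,10,9,6,11,7,-1,-1,-1,-1,-1,-1,-1},
 {6,11,7,2,10,3,10,8,3,10,9,8,-1,-1,-1,-1},
 {7,2,3,6,2,7,-1,-1,-1,-1,-1,-1,-1,-1,-1,-1},
 {7,0,8,7,6,0,6,2,0,-1,-1,-1,-1,-1,-1,-1},
 {2,7,6,2,3,7,0,1,9,-1,-1,-1,-1,-1,-1,-1},
 {1,6,2,1,8,6,1,9,8,8,7,6,-1,-1,-1,-1},
 {10,7,6,10,1,7,1,3,7,-1,-1,-1,-1,-1,-1,-1},
 {10,7,6,1,7,10,1,8,7,1,0,8,-1,-1,-1,-1},
 {0,3,7,0,7,10,0,10,9,6,10,7,-1,-1,-1,-1},
 {7,6,10,7,10,8,8,10,9,-1,-1,-1,-1,-1,-1,-1},
 {6,8,4,11,8,6,-1,-1,-1,-1,-1,-1,-1,-1,-1,-1},
 {3,6,11,3,0,6,0,4,6,-1,-1,-1,-1,-1,-1,-1},
 {8,6,11,8,4,6,9,0,1,-1,-1,-1,-1,-1,-1,-1},
 {9,4,6,9,6,3,9,3,1,11,3,6,-1,-1,-1,-1},
 {6,8,4,6,11,8,2,10,1,-1,-1,-1,-1,-1,-1,-1},
 {1,2,10,3,0,11,0,6,11,0,4,6,-1,-1,-1,-1},
 {4,11,8,4,6,11,0,2,9,2,10,9,-1,-1,-1,-1},
 {10,9,3,10,3,2,9,4,3,11,3,6,4,6,3,-1},
 {8,2,3,8,4,2,4,6,2,-1,-1,-1,-1,-1,-1,-1},
 {0,4,2,4,6,2,-1,-1,-1,-1,-1,-1,-1,-1,-1,-1},
 {1,9,0,2,3,4,2,4,6,4,3,8,-1,-1,-1,-1},
 {1,9,4,1,4,2,2,4,6,-1,-1,-1,-1,-1,-1,-1},
 {8,1,3,8,6,1,8,4,6,6,10,1,-1,-1,-1,-1},
 {10,1,0,10,0,6,6,0,4,-1,-1,-1,-1,-1,-1,-1},
 {4,6,3,4,3,8,6,10,3,0,3,9,10,9,3,-1},
 {10,9,4,6,10,4,-1,-1,-1,-1,-1,-1,-1,-1,-1,-1},
 {4,9,5,7,6,11,-1,-1,-1,-1,-1,-1,-1,-1,-1,-1},
 {0,8,3,4,9,5,11,7,6,-1,-1,-1,-1,-1,-1,-1},
 {5,0,1,5,4,0,7,6,11,-1,-1,-1,-1,-1,-1,-1},
 {11,7,6,8,3,4,3,5,4,3,1,5,-1,-1,-1,-1},
 {9,5,4,10,1,2,7,6,11,-1,-1,-1,-1,-1,-1,-1},
 {6,11,7,1,2,10,0,8,3,4,9,5,-1,-1,-1,-1},
 {7,6,11,5,4,10,4,2,10,4,0,2,-1,-1,-1,-1},
 {3,4,8,3,5,4,3,2,5,10,5,2,11,7,6,-1},
 {7,2,3,7,6,2,5,4,9,-1,-1,-1,-1,-1,-1,-1},
 {9,5,4,0,8,6,0,6,2,6,8,7,-1,-1,-1,-1},
 {3,6,2,3,7,6,1,5,0,5,4,0,-1,-1,-1,-1},
 {6,2,8,6,8,7,2,1,8,4,8,5,1,5,8,-1},
 {9,5,4,10,1,6,1,7,6,1,3,7,-1,-1,-1,-1},
 {1,6,10,1,7,6,1,0,7,8,7,0,9,5,4,-1},
 {4,0,10,4,10,5,0,3,10,6,10,7,3,7,10,-1},
 {7,6,10,7,10,8,5,4,10,4,8,10,-1,-1,-1,-1},
 {6,9,5,6,11,9,11,8,9,-1,-1,-1,-1,-1,-1,-1},
 {3,6,11,0,6,3,0,5,6,0,9,5,-1,-1,-1,-1},
 {0,11,8,0,5,11,0,1,5,5,6,11,-1,-1,-1,-1},
 {6,11,3,6,3,5,5,3,1,-1,-1,-1,-1,-1,-1,-1},
 {1,2,10,9,5,11,9,11,8,11,5,6,-1,-1,-1,-1},
 {0,11,3,0,6,11,0,9,6,5,6,9,1,2,10,-1},
 {11,8,5,11,5,6,8,0,5,10,5,2,0,2,5,-1},
 {6,11,3,6,3,5,2,10,3,10,5,3,-1,-1,-1,-1},
 {5,8,9,5,2,8,5,6,2,3,8,2,-1,-1,-1,-1},
 {9,5,6,9,6,0,0,6,2,-1,-1,-1,-1,-1,-1,-1},
 {1,5,8,1,8,0,5,6,8,3,8,2,6,2,8,-1},
 {1,5,6,2,1,6,-1,-1,-1,-1,-1,-1,-1,-1,-1,-1},
 {1,3,6,1,6,10,3,8,6,5,6,9,8,9,6,-1},
 {10,1,0,10,0,6,9,5,0,5,6,0,-1,-1,-1,-1},
 {0,3,8,5,6,10,-1,-1,-1,-1,-1,-1,-1,-1,-1,-1},
 {10,5,6,-1,-1,-1,-1,-1,-1,-1,-1,-1,-1,-1,-1,-1},
 {11,5,10,7,5,11,-1,-1,-1,-1,-1,-1,-1,-1,-1,-1},
 {11,5,10,11,7,5,8,3,0,-1,-1,-1,-1,-1,-1,-1},
 {5,11,7,5,10,11,1,9,0,-1,-1,-1,-1,-1,-1,-1},
 {10,7,5,10,11,7,9,8,1,8,3,1,-1,-1,-1,-1},
 {11,1,2,11,7,1,7,5,1,-1,-1,-1,-1,-1,-1,-1},
 {0,8,3,1,2,7,1,7,5,7,2,11,-1,-1,-1,-1},
 {9,7,5,9,2,7,9,0,2,2,11,7,-1,-1,-1,-1},
 {7,5,2,7,2,11,5,9,2,3,2,8,9,8,2,-1},
 {2,5,10,2,3,5,3,7,5,-1,-1,-1,-1,-1,-1,-1},
 {8,2,0,8,5,2,8,7,5,10,2,5,-1,-1,-1,-1},
 {9,0,1,5,10,3,5,3,7,3,10,2,-1,-1,-1,-1},
 {9,8,2,9,2,1,8,7,2,10,2,5,7,5,2,-1},
 {1,3,5,3,7,5,-1,-1,-1,-1,-1,-1,-1,-1,-1,-1},
 {0,8,7,0,7,1,1,7,5,-1,-1,-1,-1,-1,-1,-1},
 {9,0,3,9,3,5,5,3,7,-1,-1,-1,-1,-1,-1,-1},
 {9,8,7,5,9,7,-1,-1,-1,-1,-1,-1,-1,-1,-1,-1},
 {5,8,4,5,10,8,10,11,8,-1,-1,-1,-1,-1,-1,-1},
 {5,0,4,5,11,0,5,10,11,11,3,0,-1,-1,-1,-1},
 {0,1,9,8,4,10,8,10,11,10,4,5,-1,-1,-1,-1},
 {10,11,4,10,4,5,11,3,4,9,4,1,3,1,4,-1},
 {2,5,1,2,8,5,2,11,8,4,5,8,-1,-1,-1,-1},
 {0,4,11,0,11,3,4,5,11,2,11,1,5,1,11,-1},
 {0,2,5,0,5,9,2,11,5,4,5,8,11,8,5,-1},
 {9,4,5,2,11,3,-1,-1,-1,-1,-1,-1,-1,-1,-1,-1},
 {2,5,10,3,5,2,3,4,5,3,8,4,-1,-1,-1,-1},
 {5,10,2,5,2,4,4,2,0,-1,-1,-1,-1,-1,-1,-1},
 {3,10,2,3,5,10,3,8,5,4,5,8,0,1,9,-1},
 {5,10,2,5,2,4,1,9,2,9,4,2,-1,-1,-1,-1},
 {8,4,5,8,5,3,3,5,1,-1,-1,-1,-1,-1,-1,-1},
 {0,4,5,1,0,5,-1,-1,-1,-1,-1,-1,-1,-1,-1,-1},
 {8,4,5,8,5,3,9,0,5,0,3,5,-1,-1,-1,-1},
 {9,4,5,-1,-1,-1,-1,-1,-1,-1,-1,-1,-1,-1,-1,-1},
 {4,11,7,4,9,11,9,10,11,-1,-1,-1,-1,-1,-1,-1},
 {0,8,3,4,9,7,9,11,7,9,10,11,-1,-1,-1,-1},
 {1,10,11,1,11,4,1,4,0,7,4,11,-1,-1,-1,-1},
 {3,1,4,3,4,8,1,10,4,7,4,11,10,11,4,-1},
 {4,11,7,9,11,4,9,2,11,9,1,2,-1,-1,-1,-1},
 {9,7,4,9,11,7,9,1,11,2,11,1,0,8,3,-1},
 {11,7,4,11,4,2,2,4,0,-1,-1,-1,-1,-1,-1,-1},
 {11,7,4,11,4,2,8,3,4,3,2,4,-1,-1,-1,-1},
 {2,9,10,2,7,9,2,3,7,7,4,9,-1,-1,-1,-1},
 {9,10,7,9,7,4,10,2,7,8,7,0,2,0,7,-1},
 {3,7,10,3,10,2,7,4,10,1,10,0,4,0,10,-1},
 {1,10,2,8,7,4,-1,-1,-1,-1,-1,-1,-1,-1,-1,-1},
 {4,9,1,4,1,7,7,1,3,-1,-1,-1,-1,-1,-1,-1},
 {4,9,1,4,1,7,0,8,1,8,7,1,-1,-1,-1,-1},
 {4,0,3,7,4,3,-1,-1,-1,-1,-1,-1,-1,-1,-1,-1},
 {4,8,7,-1,-1,-1,-1,-1,-1,-1,-1,-1,-1,-1,-1,-1},
 {9,10,8,10,11,8,-1,-1,-1,-1,-1,-1,-1,-1,-1,-1},
 {3,0,9,3,9,11,11,9,10,-1,-1,-1,-1,-1,-1,-1},
 {0,1,10,0,10,8,8,10,11,-1,-1,-1,-1,-1,-1,-1},
 {3,1,10,11,3,10,-1,-1,-1,-1,-1,-1,-1,-1,-1,-1},
 {1,2,11,1,11,9,9,11,8,-1,-1,-1,-1,-1,-1,-1},
 {3,0,9,3,9,11,1,2,9,2,11,9,-1,-1,-1,-1},
 {0,2,11,8,0,11,-1,-1,-1,-1,-1,-1,-1,-1,-1,-1},
 {3,2,11,-1,-1,-1,-1,-1,-1,-1,-1,-1,-1,-1,-1,-1},
 {2,3,8,2,8,10,10,8,9,-1,-1,-1,-1,-1,-1,-1},
 {9,10,2,0,9,2,-1,-1,-1,-1,-1,-1,-1,-1,-1,-1},
 {2,3,8,2,8,10,0,1,8,1,10,8,-1,-1,-1,-1},
 {1,10,2,-1,-1,-1,-1,-1,-1,-1,-1,-1,-1,-1,-1,-1},
 {1,3,8,9,1,8,-1,-1,-1,-1,-1,-1,-1,-1,-1,-1},
 {0,9,1,-1,-1,-1,-1,-1,-1,-1,-1,-1,-1,-1,-1,-1},
 {0,3,8,-1,-1,-1,-1,-1,-1,-1,-1,-1,-1,-1,-1,-1},
 {-1,-1,-1,-1,-1,-1,-1,-1,-1,-1,-1,-1,-1,-1,-1,-1}
};

static const int CX[8] = {0,1,1,0,0,1,1,0};
static const int CY[8] = {0,0,1,1,0,0,1,1};
static const int CZ[8] = {0,0,0,0,1,1,1,1};
static const int EA[12] = {0,1,2,3,4,5,6,7,0,1,2,3};
static const int EB[12] = {1,2,3,0,5,6,7,4,4,5,6,7};

// [[Rcpp::export(name = ".mcCore")]]
List mcCore(NumericVector vol, IntegerVector dims, double iso) {
  const int n1 = dims[0], n2 = dims[1], n3 = dims[2];
  const double *v = REAL(vol);
  const long long s1 = 1, s2 = n1, s3 = (long long)n1 * n2;

  std::unordered_map<long long, int> edgeVertex;
  std::vector<double> verts;          // x,y,z triples, 0-based index space
  std::vector<int> tris;              // 1-based vertex ids

  double cv[8];
  long long cid[8];

  for (int k = 0; k < n3 - 1; ++k)
    for (int j = 0; j < n2 - 1; ++j)
      for (int i = 0; i < n1 - 1; ++i) {
        int caseIdx = 0;
        for (int c = 0; c < 8; ++c) {
          cid[c] = (i + CX[c]) * s1 + (j + CY[c]) * s2 + (k + CZ[c]) * s3;
          cv[c] = v[cid[c]];
          if (cv[c] < iso) caseIdx |= (1 << c);
        }
        if (caseIdx == 0 || caseIdx == 255) continue;
        const signed char *row = TRI_TABLE[caseIdx];
        for (int t = 0; row[t] != -1; t += 3) {
          int ids[3];
          for (int e = 0; e < 3; ++e) {
            const int edge = row[t + e];
            const int a = EA[edge], b = EB[edge];
            const long long ia = cid[a], ib = cid[b];
            // canonical key: smaller endpoint id + axis of the edge
            const long long lo = ia < ib ? ia : ib;
            const long long diff = ia < ib ? ib - ia : ia - ib;
            const int axis = diff == s1 ? 0 : (diff == s2 ? 1 : 2);
            const long long key = lo * 3 + axis;
            auto it = edgeVertex.find(key);
            if (it != edgeVertex.end()) {
              ids[e] = it->second;
            } else {
              const double va = cv[a], vb = cv[b];
              double f = (iso - va) / (vb - va);
              if (f < 0) f = 0; else if (f > 1) f = 1;
              const double px = (i + CX[a]) + f * (CX[b] - CX[a]);
              const double py = (j + CY[a]) + f * (CY[b] - CY[a]);
              const double pz = (k + CZ[a]) + f * (CZ[b] - CZ[a]);
              const int id = (int)(verts.size() / 3) + 1;
              verts.push_back(px); verts.push_back(py); verts.push_back(pz);
              edgeVertex.emplace(key, id);
              ids[e] = id;
            }
          }
          tris.push_back(ids[0]); tris.push_back(ids[1]);
          tris.push_back(ids[2]);
        }
      }

  const int nv = (int)(verts.size() / 3), nt = (int)(tris.size() / 3);
  NumericMatrix V(nv, 3);
  for (int r = 0; r < nv; ++r) {
    V(r, 0) = verts[3 * r]; V(r, 1) = verts[3 * r + 1];
    V(r, 2) = verts[3 * r + 2];
  }
  IntegerMatrix Tm(nt, 3);
  for (int r = 0; r < nt; ++r) {
    Tm(r, 0) = tris[3 * r]; Tm(r, 1) = tris[3 * r + 1];
    Tm(r, 2) = tris[3 * r + 2];
  }
  return List::create(_["vertices"] = V, _["triangles"] = Tm);
}
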