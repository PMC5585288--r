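#include <Rcpp.h>
#include <vector>
#include <algorithm>
#include <cstring>
using namespace Rcpp;

// 3D curve thinning by sequential removal of simple points, ordered by a
// priority field (typically the Euclidean distance map, so erosion proceeds
// from the object surface inwards). A voxel is simple iff its removal
// preserves topology, characterised by the topological numbers
// T26(p, object) == 1 and T6(p, background) == 1 (the latter evaluated in
// the 18-neighbourhood). Curve endpoints (<= 1 object neighbour) are kept,
// so fibre tips are not eroded away.

namespace {

struct Off { int dx, dy, dz; };

// all 26 neighbourhood offsets (max-norm 1, excluding centre)
static Off OFF26[26];
// indices (into OFF26) of the 18-neighbourhood (L1 norm <= 2)
static int IDX18[18];
static int N18;
// indices of the 6 face neighbours (L1 norm == 1)
static bool ISFACE[26];
// adjacency lists within the 26-neighbourhood
static std::vector<int> ADJ26[26]; // 26-adjacency between offsets
static std::vector<int> ADJ6[26];  // 6-adjacency between offsets
static bool tables_ready = false;

static void build_tables() {
  if (tables_ready) return;
  int n = 0;
  for (int dz = -1; dz <= 1; ++dz)
    for (int dy = -1; dy <= 1; ++dy)
      for (int dx = -1; dx <= 1; ++dx) {
        if (dx == 0 && dy == 0 && dz == 0) continue;
        OFF26[n].dx = dx; OFF26[n].dy = dy; OFF26[n].dz = dz;
        ++n;
      }
  N18 = 0;
  for (int a = 0; a < 26; ++a) {
    const int l1 = std::abs(OFF26[a].dx) + std::abs(OFF26[a].dy) + std::abs(OFF26[a].dz);
    ISFACE[a] = (l1 == 1);
    if (l1 <= 2) IDX18[N18++] = a;
  }
  for (int a = 0; a < 26; ++a)
    for (int b = 0; b < 26; ++b) {
      if (a == b) continue;
      const int ddx = std::abs(OFF26[a].dx - OFF26[b].dx);
      const int ddy = std::abs(OFF26[a].dy - OFF26[b].dy);
      const int ddz = std::abs(OFF26[a].dz - OFF26[b].dz);
      const int linf = std::max(ddx, std::max(ddy, ddz));
      const int l1 = ddx + ddy + ddz;
      if (linf <= 1) ADJ26[a].push_back(b);
      if (l1 == 1) ADJ6[a].push_back(b);
    }
  tables_ready = true;
}

// number of 26-connected components of object voxels in the 26-neighbourhood
static int T26(const bool nb[26]) {
  bool seen[26] = {false};
  int comps = 0, stack[26];
  for (int a = 0; a < 26; ++a) {
    if (!nb[a] || seen[a]) continue;
    ++comps;
    int top = 0;
    stack[top++] = a;
    seen[a] = true;
    while (top) {
      const int c = stack[--top];
      for (size_t q = 0; q < ADJ26[c].size(); ++q) {
        const int b = ADJ26[c][q];
        if (nb[b] && !seen[b]) { seen[b] = true; stack[top++] = b; }
      }
    }
  }
  return comps;
}

// number of 6-connected components of background voxels within the
// 18-neighbourhood that contain at least one face neighbour
static int T6bar(const bool nb[26]) {
  bool in18[26] = {false};
  for (int q = 0; q < N18; ++q) in18[IDX18[q]] = true;
  bool seen[26] = {false};
  int comps = 0, stack[26];
  for (int qi = 0; qi < N18; ++qi) {
    const int a = IDX18[qi];
    if (nb[a] || seen[a] || !ISFACE[a]) continue; // seed from face neighbours
    ++comps;
    int top = 0;
    stack[top++] = a;
    seen[a] = true;
    while (top) {
      const int c = stack[--top];
      for (size_t q = 0; q < ADJ6[c].size(); ++q) {
        const int b = ADJ6[c][q];
        if (in18[b] && !nb[b] && !seen[b]) { seen[b] = true; stack[top++] = b; }
      }
    }
  }
  return comps;
}

class Grid {
public:
  Grid(int* data, int n1, int n2, int n3) : d(data), n1(n1), n2(n2), n3(n3) {}
  inline bool at(int x, int y, int z) const {
    if (x < 0 || y < 0 || z < 0 || x >= n1 || y >= n2 || z >= n3) return false;
    return d[(R_xlen_t)x + (R_xlen_t)n1 * (y + (R_xlen_t)n2 * z)] != 0;
  }
  inline void clear(int x, int y, int z) {
    d[(R_xlen_t)x + (R_xlen_t)n1 * (y + (R_xlen_t)n2 * z)] = 0;
  }
  int* d;
  int n1, n2, n3;
};

static void neighbourhood(const Grid& g, int x, int y, int z, bool nb[26]) {
  for (int a = 0; a < 26; ++a)
    nb[a] = g.at(x + OFF26[a].dx, y + OFF26[a].dy, z + OFF26[a].dz);
}

static inline int nObjNeighbours(const bool nb[26]) {
  int c = 0;
  for (int a = 0; a < 26; ++a) c += nb[a];
  return c;
}

static inline bool isSimple(const bool nb[26]) {
  return T26(nb) == 1 && T6bar(nb) == 1;
}

} // namespace

// Six directional sub-iterations per pass: in each sub-pass only object
// voxels whose face neighbour in the current direction is background are
// candidates, collected at sub-pass start, processed in increasing priority
// order and re-checked for simplicity at deletion time. The directional
// split prevents a single pass from zipping through 2-voxel-wide structures.
// [[Rcpp::export]]
IntegerVector thin3d_cpp(IntegerVector mask, IntegerVector dims,
                         NumericVector priority) {
  build_tables();
  const int n1 = dims[0], n2 = dims[1], n3 = dims[2];
  IntegerVector out = clone(mask);
  Grid g(INTEGER(out), n1, n2, n3);

  static const int DIR[6][3] = {{0, 0, -1}, {0, 0, 1}, {0, -1, 0},
                                {0, 1, 0}, {-1, 0, 0}, {1, 0, 0}};
  typedef std::pair<double, R_xlen_t> Cand; // (priority, linear index)
  std::vector<R_xlen_t> object;
  for (int z = 0; z < n3; ++z)
    for (int y = 0; y < n2; ++y)
      for (int x = 0; x < n1; ++x)
        if (g.at(x, y, z))
          object.push_back((R_xlen_t)x + (R_xlen_t)n1 * (y + (R_xlen_t)n2 * z));

  bool nb[26];
  bool changed = true;
  while (changed) {
    changed = false;
    for (int d = 0; d < 6; ++d) {
      std::vector<Cand> cand;
      for (size_t q = 0; q < object.size(); ++q) {
        const R_xlen_t id = object[q];
        const int x = (int)(id % n1);
        const int y = (int)((id / n1) % n2);
        const int z = (int)(id / ((R_xlen_t)n1 * n2));
        if (!g.at(x, y, z)) continue;
        if (!g.at(x + DIR[d][0], y + DIR[d][1], z + DIR[d][2]))
          cand.push_back(Cand(priority[id], id));
      }
      std::sort(cand.begin(), cand.end());
      for (size_t q = 0; q < cand.size(); ++q) {
        const R_xlen_t id = cand[q].second;
        const int x = (int)(id % n1);
        const int y = (int)((id / n1) % n2);
        const int z = (int)(id / ((R_xlen_t)n1 * n2));
        if (!g.at(x, y, z)) continue;
        neighbourhood(g, x, y, z, nb);
        if (nObjNeighbours(nb) <= 1) continue; // curve endpoint: keep
        if (!isSimple(nb)) continue;
        g.clear(x, y, z);
        changed = true;
      }
    }
    // compact the object list between passes
    std::vector<R_xlen_t> still;
    still.reserve(object.size());
    for (size_t q = 0; q < object.size(); ++q)
      if (out[object[q]]) still.push_back(object[q]);
    object.swap(still);
  }
  return out;
}
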