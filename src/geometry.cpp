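// Geometric kernels: closest point on a triangle mesh (grid-indexed),
// exact Euclidean distance transform, exterior flood fill, and marching
// tetrahedra isosurface extraction on a node grid.

#include <Rcpp.h>
#include <cmath>
#include <vector>
#include <unordered_map>
#include <limits>
using namespace Rcpp;

static const double BIG = std::numeric_limits<double>::max() / 4.0;

// Closest point on triangle abc to p (Ericson, Real-Time Collision Detection).
static inline void closest_pt_tri(const double p[3], const double a[3],
                                  const double b[3], const double c[3],
                                  double out[3]) {
  double ab[3], ac[3], ap[3];
  for (int i = 0; i < 3; i++) { ab[i] = b[i]-a[i]; ac[i] = c[i]-a[i]; ap[i] = p[i]-a[i]; }
  double d1 = ab[0]*ap[0]+ab[1]*ap[1]+ab[2]*ap[2];
  double d2 = ac[0]*ap[0]+ac[1]*ap[1]+ac[2]*ap[2];
  if (d1 <= 0.0 && d2 <= 0.0) { for (int i=0;i<3;i++) out[i]=a[i]; return; }
  double bp[3]; for (int i=0;i<3;i++) bp[i]=p[i]-b[i];
  double d3 = ab[0]*bp[0]+ab[1]*bp[1]+ab[2]*bp[2];
  double d4 = ac[0]*bp[0]+ac[1]*bp[1]+ac[2]*bp[2];
  if (d3 >= 0.0 && d4 <= d3) { for (int i=0;i<3;i++) out[i]=b[i]; return; }
  double vc = d1*d4 - d3*d2;
  if (vc <= 0.0 && d1 >= 0.0 && d3 <= 0.0) {
    double v = d1 / (d1 - d3);
    for (int i=0;i<3;i++) out[i]=a[i]+v*ab[i]; return;
  }
  double cp[3]; for (int i=0;i<3;i++) cp[i]=p[i]-c[i];
  double d5 = ab[0]*cp[0]+ab[1]*cp[1]+ab[2]*cp[2];
  double d6 = ac[0]*cp[0]+ac[1]*cp[1]+ac[2]*cp[2];
  if (d6 >= 0.0 && d5 <= d6) { for (int i=0;i<3;i++) out[i]=c[i]; return; }
  double vb = d5*d2 - d1*d6;
  if (vb <= 0.0 && d2 >= 0.0 && d6 <= 0.0) {
    double w = d2 / (d2 - d6);
    for (int i=0;i<3;i++) out[i]=a[i]+w*ac[i]; return;
  }
  double va = d3*d6 - d5*d4;
  if (va <= 0.0 && (d4 - d3) >= 0.0 && (d5 - d6) >= 0.0) {
    double w = (d4 - d3) / ((d4 - d3) + (d5 - d6));
    for (int i=0;i<3;i++) out[i]=b[i]+w*(c[i]-b[i]); return;
  }
  double denom = 1.0 / (va + vb + vc);
  double v = vb * denom, w = vc * denom;
  for (int i=0;i<3;i++) out[i]=a[i]+ab[i]*v+ac[i]*w;
}

// [[Rcpp::export]]
List cpp_closest_on_mesh(NumericMatrix P, NumericMatrix V, IntegerMatrix F) {
  const int np = P.nrow(), nv = V.nrow(), nf = F.nrow();
  if (nf == 0) stop("target mesh has no faces");
  double lo[3], hi[3];
  for (int k = 0; k < 3; k++) { lo[k] = BIG; hi[k] = -BIG; }
  for (int i = 0; i < nv; i++)
    for (int k = 0; k < 3; k++) {
      double x = V(i, k);
      if (x < lo[k]) lo[k] = x;
      if (x > hi[k]) hi[k] = x;
    }
  int ng = (int) std::ceil(std::cbrt((double) nf / 2.0));
  if (ng < 1) ng = 1;
  if (ng > 64) ng = 64;
  double cs[3];
  for (int k = 0; k < 3; k++) {
    cs[k] = (hi[k] - lo[k]) / ng;
    if (cs[k] <= 0) cs[k] = 1.0;
  }
  // bucket triangles by AABB overlap
  std::vector< std::vector<int> > cells((size_t) ng * ng * ng);
  for (int t = 0; t < nf; t++) {
    double tlo[3], thi[3];
    for (int k = 0; k < 3; k++) { tlo[k] = BIG; thi[k] = -BIG; }
    for (int j = 0; j < 3; j++) {
      int vi = F(t, j);
      for (int k = 0; k < 3; k++) {
        double x = V(vi, k);
        if (x < tlo[k]) tlo[k] = x;
        if (x > thi[k]) thi[k] = x;
      }
    }
    int c0[3], c1[3];
    for (int k = 0; k < 3; k++) {
      c0[k] = (int) std::floor((tlo[k] - lo[k]) / cs[k]);
      c1[k] = (int) std::floor((thi[k] - lo[k]) / cs[k]);
      if (c0[k] < 0) c0[k] = 0; if (c0[k] > ng-1) c0[k] = ng-1;
      if (c1[k] < 0) c1[k] = 0; if (c1[k] > ng-1) c1[k] = ng-1;
    }
    for (int x = c0[0]; x <= c1[0]; x++)
      for (int y = c0[1]; y <= c1[1]; y++)
        for (int z = c0[2]; z <= c1[2]; z++)
          cells[(size_t) x + ng * (y + (size_t) ng * z)].push_back(t);
  }
  NumericVector dist(np);
  NumericMatrix foot(np, 3);
  IntegerVector tri(np);
  std::vector<int> stamp(nf, -1);
  double q[3], a[3], b[3], c[3], cp[3], bestp[3];
  for (int ip = 0; ip < np; ip++) {
    for (int k = 0; k < 3; k++) q[k] = P(ip, k);
    int cc[3];
    for (int k = 0; k < 3; k++) {
      cc[k] = (int) std::floor((q[k] - lo[k]) / cs[k]);
      if (cc[k] < 0) cc[k] = 0; if (cc[k] > ng-1) cc[k] = ng-1;
    }
    double best = BIG; int bestt = -1;
    for (int r = 0; ; r++) {
      int x0 = cc[0]-r, x1 = cc[0]+r, y0 = cc[1]-r, y1 = cc[1]+r, z0 = cc[2]-r, z1 = cc[2]+r;
      bool anycell = false;
      for (int x = std::max(x0,0); x <= std::min(x1,ng-1); x++)
        for (int y = std::max(y0,0); y <= std::min(y1,ng-1); y++)
          for (int z = std::max(z0,0); z <= std::min(z1,ng-1); z++) {
            int ring = std::max(std::abs(x-cc[0]), std::max(std::abs(y-cc[1]), std::abs(z-cc[2])));
            if (ring != r) continue;
            anycell = true;
            const std::vector<int>& tl = cells[(size_t) x + ng * (y + (size_t) ng * z)];
            for (size_t it = 0; it < tl.size(); it++) {
              int t = tl[it];
              if (stamp[t] == ip) continue;
              stamp[t] = ip;
              for (int k = 0; k < 3; k++) {
                a[k] = V(F(t,0), k); b[k] = V(F(t,1), k); c[k] = V(F(t,2), k);
              }
              closest_pt_tri(q, a, b, c, cp);
              double d2 = 0.0;
              for (int k = 0; k < 3; k++) { double dd = cp[k]-q[k]; d2 += dd*dd; }
              if (d2 < best) {
                best = d2; bestt = t;
                for (int k = 0; k < 3; k++) bestp[k] = cp[k];
              }
            }
          }
      // min distance from q to any cell outside the explored box
      double dbound = BIG;
      if (x0 > 0)     dbound = std::min(dbound, q[0] - (lo[0] + x0 * cs[0]));
      if (x1 < ng-1)  dbound = std::min(dbound, lo[0] + (x1+1) * cs[0] - q[0]);
      if (y0 > 0)     dbound = std::min(dbound, q[1] - (lo[1] + y0 * cs[1]));
      if (y1 < ng-1)  dbound = std::min(dbound, lo[1] + (y1+1) * cs[1] - q[1]);
      if (z0 > 0)     dbound = std::min(dbound, q[2] - (lo[2] + z0 * cs[2]));
      if (z1 < ng-1)  dbound = std::min(dbound, lo[2] + (z1+1) * cs[2] - q[2]);
      bool covered = (x0 <= 0 && y0 <= 0 && z0 <= 0 && x1 >= ng-1 && y1 >= ng-1 && z1 >= ng-1);
      if (bestt >= 0 && (dbound < 0 ? false : best <= dbound * dbound)) break;
      if (covered) break;
      (void) anycell;
    }
    dist[ip] = std::sqrt(best);
    tri[ip] = bestt;                  // 0-based; caller adds 1
    for (int k = 0; k < 3; k++) foot(ip, k) = bestp[k];
  }
  return List::create(_["dist"] = dist, _["foot"] = foot, _["tri"] = tri);
}

// 1-D squared distance transform (Felzenszwalb & Huttenlocher).
static void dt1d(const std::vector<double>& f, int n, std::vector<double>& d,
                 std::vector<int>& v, std::vector<double>& z) {
  int k = 0;
  v[0] = 0;
  z[0] = -BIG; z[1] = BIG;
  for (int q = 1; q < n; q++) {
    double s;
    while (true) {
      s = ((f[q] + q*(double)q) - (f[v[k]] + v[k]*(double)v[k])) / (2.0*q - 2.0*v[k]);
      if (s <= z[k]) k--; else break;
    }
    k++;
    v[k] = q;
    z[k] = s; z[k+1] = BIG;
  }
  k = 0;
  for (int q = 0; q < n; q++) {
    while (z[k+1] < q) k++;
    double dq = q - (double) v[k];
    d[q] = dq*dq + f[v[k]];
  }
}

// Distance (in voxel units) from every node to the nearest seed node.
// [[Rcpp::export]]
NumericVector cpp_edt3d(LogicalVector seed, IntegerVector dims) {
  const int nx = dims[0], ny = dims[1], nz = dims[2];
  const size_t n = (size_t) nx * ny * nz;
  NumericVector out(n);
  std::vector<double> g(n);
  for (size_t i = 0; i < n; i++) g[i] = seed[i] ? 0.0 : BIG;
  int nmax = std::max(nx, std::max(ny, nz));
  std::vector<double> f(nmax), d(nmax), z(nmax + 1);
  std::vector<int> v(nmax);
  // pass along x
  for (int zz = 0; zz < nz; zz++)
    for (int yy = 0; yy < ny; yy++) {
      size_t base = (size_t) nx * (yy + (size_t) ny * zz);
      for (int xx = 0; xx < nx; xx++) f[xx] = g[base + xx];
      dt1d(f, nx, d, v, z);
      for (int xx = 0; xx < nx; xx++) g[base + xx] = d[xx];
    }
  // pass along y
  for (int zz = 0; zz < nz; zz++)
    for (int xx = 0; xx < nx; xx++) {
      size_t base = xx + (size_t) nx * ny * zz;
      for (int yy = 0; yy < ny; yy++) f[yy] = g[base + (size_t) nx * yy];
      dt1d(f, ny, d, v, z);
      for (int yy = 0; yy < ny; yy++) g[base + (size_t) nx * yy] = d[yy];
    }
  // pass along z
  for (int yy = 0; yy < ny; yy++)
    for (int xx = 0; xx < nx; xx++) {
      size_t base = xx + (size_t) nx * yy;
      size_t stride = (size_t) nx * ny;
      for (int zz = 0; zz < nz; zz++) f[zz] = g[base + stride * zz];
      dt1d(f, nz, d, v, z);
      for (int zz = 0; zz < nz; zz++) g[base + stride * zz] = d[zz];
    }
  for (size_t i = 0; i < n; i++) out[i] = std::sqrt(g[i]);
  return out;
}

// Nodes of `open` reachable from the grid boundary through 6-connected
// open nodes (used to tell exterior from enclosed interior).
// [[Rcpp::export]]
LogicalVector cpp_flood_exterior(LogicalVector open, IntegerVector dims) {
  const int nx = dims[0], ny = dims[1], nz = dims[2];
  const size_t n = (size_t) nx * ny * nz;
  LogicalVector out(n);
  std::vector<char> vis(n, 0);
  std::vector<size_t> queue;
  queue.reserve(n / 8 + 64);
  for (int zz = 0; zz < nz; zz++)
    for (int yy = 0; yy < ny; yy++)
      for (int xx = 0; xx < nx; xx++) {
        if (xx != 0 && xx != nx-1 && yy != 0 && yy != ny-1 && zz != 0 && zz != nz-1) continue;
        size_t id = xx + (size_t) nx * (yy + (size_t) ny * zz);
        if (open[id] && !vis[id]) { vis[id] = 1; queue.push_back(id); }
      }
  size_t head = 0;
  while (head < queue.size()) {
    size_t id = queue[head++];
    int xx = id % nx, yy = (id / nx) % ny, zz = id / ((size_t) nx * ny);
    const int dx[6] = {1,-1,0,0,0,0}, dy[6] = {0,0,1,-1,0,0}, dz[6] = {0,0,0,0,1,-1};
    for (int k = 0; k < 6; k++) {
      int x2 = xx+dx[k], y2 = yy+dy[k], z2 = zz+dz[k];
      if (x2 < 0 || x2 >= nx || y2 < 0 || y2 >= ny || z2 < 0 || z2 >= nz) continue;
      size_t id2 = x2 + (size_t) nx * (y2 + (size_t) ny * z2);
      if (open[id2] && !vis[id2]) { vis[id2] = 1; queue.push_back(id2); }
    }
  }
  for (size_t i = 0; i < n; i++) out[i] = (vis[i] != 0);
  return out;
}

struct MTState {
  std::vector<double> verts;
  std::vector<int> faces;
  std::unordered_map<long long, int> edgev;
};

static int edge_vertex(MTState& st, size_t g0, size_t g1, double f0, double f1,
                       const double p0[3], const double p1[3]) {
  size_t ga = g0, gb = g1;
  double fa = f0, fb = f1;
  const double *pa = p0, *pb = p1;
  if (ga > gb) { std::swap(ga, gb); std::swap(fa, fb); std::swap(pa, pb); }
  long long key = ((long long) ga << 32) | (long long) gb;
  std::unordered_map<long long, int>::iterator it = st.edgev.find(key);
  if (it != st.edgev.end()) return it->second;
  double t = fa / (fa - fb);
  if (t < 1e-6) t = 1e-6;
  if (t > 1.0 - 1e-6) t = 1.0 - 1e-6;
  int id = (int) (st.verts.size() / 3);
  for (int k = 0; k < 3; k++) st.verts.push_back(pa[k] + t * (pb[k] - pa[k]));
  st.edgev[key] = id;
  return id;
}

static void emit_tri(MTState& st, int i1, int i2, int i3, const double ref[3], bool toward) {
  // orient so the normal points away from `ref` (toward = false) or toward it
  const double *p1 = &st.verts[3*(size_t)i1], *p2 = &st.verts[3*(size_t)i2], *p3 = &st.verts[3*(size_t)i3];
  double u[3], v[3], nrm[3], cen[3];
  for (int k = 0; k < 3; k++) {
    u[k] = p2[k]-p1[k]; v[k] = p3[k]-p1[k];
    cen[k] = (p1[k]+p2[k]+p3[k])/3.0;
  }
  nrm[0] = u[1]*v[2]-u[2]*v[1];
  nrm[1] = u[2]*v[0]-u[0]*v[2];
  nrm[2] = u[0]*v[1]-u[1]*v[0];
  double dot = 0.0;
  for (int k = 0; k < 3; k++) dot += nrm[k] * (cen[k] - ref[k]);
  bool flip = toward ? (dot > 0) : (dot < 0);
  if (flip) std::swap(i2, i3);
  st.faces.push_back(i1); st.faces.push_back(i2); st.faces.push_back(i3);
}

// Marching tetrahedra (Kuhn 6-tet cube split) on a node grid; surface of the
// region where field < 0. Node (ix,iy,iz) sits at origin + h*(ix,iy,iz).
// [[Rcpp::export]]
List cpp_marching_tets(NumericVector field, IntegerVector dims,
                       NumericVector origin, double h) {
  const int nx = dims[0], ny = dims[1], nz = dims[2];
  MTState st;
  const int perms[6][3] = {{0,1,2},{0,2,1},{1,0,2},{1,2,0},{2,0,1},{2,1,0}};
  int off[4][3];
  double pos[4][3], fv[4];
  size_t gid[4];
  for (int cz = 0; cz < nz-1; cz++)
    for (int cy = 0; cy < ny-1; cy++)
      for (int cx = 0; cx < nx-1; cx++) {
        // quick reject: all 8 corners same side
        bool anyneg = false, anypos = false;
        for (int dz = 0; dz < 2 && !(anyneg && anypos); dz++)
          for (int dy = 0; dy < 2; dy++)
            for (int dx = 0; dx < 2; dx++) {
              double fc = field[(cx+dx) + (size_t) nx * ((cy+dy) + (size_t) ny * (cz+dz))];
              if (fc < 0) anyneg = true; else anypos = true;
            }
        if (!(anyneg && anypos)) continue;
        for (int tp = 0; tp < 6; tp++) {
          const int *pm = perms[tp];
          off[0][0] = 0; off[0][1] = 0; off[0][2] = 0;
          for (int k = 0; k < 3; k++) off[1][k] = off[0][k];
          off[1][pm[0]] += 1;
          for (int k = 0; k < 3; k++) off[2][k] = off[1][k];
          off[2][pm[1]] += 1;
          off[3][0] = 1; off[3][1] = 1; off[3][2] = 1;
          int inside[4], nin = 0;
          for (int j = 0; j < 4; j++) {
            int ix = cx + off[j][0], iy = cy + off[j][1], iz = cz + off[j][2];
            gid[j] = ix + (size_t) nx * (iy + (size_t) ny * iz);
            fv[j] = field[gid[j]];
            pos[j][0] = origin[0] + h * ix;
            pos[j][1] = origin[1] + h * iy;
            pos[j][2] = origin[2] + h * iz;
            inside[j] = fv[j] < 0;
            nin += inside[j];
          }
          if (nin == 0 || nin == 4) continue;
          if (nin == 1 || nin == 3) {
            int apex = -1;
            for (int j = 0; j < 4; j++)
              if ((nin == 1 && inside[j]) || (nin == 3 && !inside[j])) apex = j;
            int e[3], m = 0;
            for (int j = 0; j < 4; j++) {
              if (j == apex) continue;
              e[m++] = edge_vertex(st, gid[apex], gid[j], fv[apex], fv[j], pos[apex], pos[j]);
            }
            // outward = away from inside apex, or toward outside apex
            emit_tri(st, e[0], e[1], e[2], pos[apex], nin == 3);
          } else {
            int in[2], outv[2], mi = 0, mo = 0;
            for (int j = 0; j < 4; j++) {
              if (inside[j]) in[mi++] = j; else outv[mo++] = j;
            }
            int i = in[0], j2 = in[1], k2 = outv[0], l = outv[1];
            int eik = edge_vertex(st, gid[i], gid[k2], fv[i], fv[k2], pos[i], pos[k2]);
            int eil = edge_vertex(st, gid[i], gid[l],  fv[i], fv[l],  pos[i], pos[l]);
            int ejl = edge_vertex(st, gid[j2], gid[l],  fv[j2], fv[l],  pos[j2], pos[l]);
            int ejk = edge_vertex(st, gid[j2], gid[k2], fv[j2], fv[k2], pos[j2], pos[k2]);
            double ref[3];
            for (int k = 0; k < 3; k++) ref[k] = 0.5 * (pos[i][k] + pos[j2][k]);
            emit_tri(st, eik, eil, ejl, ref, false);
            emit_tri(st, eik, ejl, ejk, ref, false);
          }
        }
      }
  int nvv = (int) (st.verts.size() / 3);
  int nff = (int) (st.faces.size() / 3);
  NumericMatrix Vout(nvv, 3);
  IntegerMatrix Fout(nff, 3);
  for (int i = 0; i < nvv; i++)
    for (int k = 0; k < 3; k++) Vout(i, k) = st.verts[3*(size_t)i + k];
  for (int i = 0; i < nff; i++)
    for (int k = 0; k < 3; k++) Fout(i, k) = st.faces[3*(size_t)i + k];
  return List::create(_["vertices"] = Vout, _["faces"] = Fout);
}

// Connected-component labels (1-based) of a vertex set under an edge list.
// [[Rcpp::export]]
IntegerVector cpp_components(IntegerMatrix edges, int nv) {
  std::vector<int> parent(nv);
  for (int i = 0; i < nv; i++) parent[i] = i;
  // iterative find with path halving
  for (int k = 0; k < edges.nrow(); k++) {
    int a = edges(k, 0) - 1, b = edges(k, 1) - 1;
    while (parent[a] != a) { parent[a] = parent[parent[a]]; a = parent[a]; }
    while (parent[b] != b) { parent[b] = parent[parent[b]]; b = parent[b]; }
    if (a != b) parent[a] = b;
  }
  IntegerVector out(nv);
  std::unordered_map<int, int> relabel;
  int next = 0;
  for (int i = 0; i < nv; i++) {
    int r = i;
    while (parent[r] != r) { parent[r] = parent[parent[r]]; r = parent[r]; }
    std::unordered_map<int,int>::iterator it = relabel.find(r);
    if (it == relabel.end()) { relabel[r] = ++next; out[i] = next; }
    else out[i] = it->second;
  }
  return out;
}

// Mark grid nodes lying within `radius` of any triangle of the mesh.
// [[Rcpp::export]]
LogicalVector cpp_stamp_triangles(NumericMatrix V, IntegerMatrix F,
                                  NumericVector origin, double h,
                                  IntegerVector dims, double radius) {
  const int nx = dims[0], ny = dims[1], nz = dims[2];
  const size_t n = (size_t) nx * ny * nz;
  LogicalVector out(n);
  double a[3], b[3], c[3], q[3], cp[3];
  const double r2 = radius * radius;
  for (int t = 0; t < F.nrow(); t++) {
    double tlo[3], thi[3];
    for (int k = 0; k < 3; k++) {
      a[k] = V(F(t,0), k); b[k] = V(F(t,1), k); c[k] = V(F(t,2), k);
      tlo[k] = std::min(a[k], std::min(b[k], c[k])) - radius;
      thi[k] = std::max(a[k], std::max(b[k], c[k])) + radius;
    }
    int i0[3], i1[3];
    for (int k = 0; k < 3; k++) {
      i0[k] = std::max(0, (int) std::ceil((tlo[k] - origin[k]) / h));
      i1[k] = std::min(dims[k] - 1, (int) std::floor((thi[k] - origin[k]) / h));
    }
    for (int iz = i0[2]; iz <= i1[2]; iz++)
      for (int iy = i0[1]; iy <= i1[1]; iy++)
        for (int ix = i0[0]; ix <= i1[0]; ix++) {
          size_t id = ix + (size_t) nx * (iy + (size_t) ny * iz);
          if (out[id]) continue;
          q[0] = origin[0] + h * ix;
          q[1] = origin[1] + h * iy;
          q[2] = origin[2] + h * iz;
          closest_pt_tri(q, a, b, c, cp);
          double d2 = 0.0;
          for (int k = 0; k < 3; k++) { double dd = cp[k]-q[k]; d2 += dd*dd; }
          if (d2 <= r2) out[id] = true;
        }
  }
  return out;
}
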