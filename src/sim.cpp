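#include <Rcpp.h>
#include <vector>
#include <string>
#include <cmath>
#include <climits>
#include <unordered_map>
#include <algorithm>
using namespace Rcpp;

int nussinov_count(const std::vector<int>& s, int minloop, bool wobble);

namespace {

const int LIFE_FOREVER = INT_MAX / 2;

struct Params {
  double sizeX, sizeY, radius, dt, D, d, seq_mut, K, rate_per_match;
  int neigh, min_loop, match_threshold, max_steps, seq_length;
  bool wobble;
  std::vector<int> motif;
  double hyd[4][4];
};

// free = 0, enzyme-in-complex = 1, template-in-complex = 2
struct Pop {
  std::vector<std::string> seq;  // bytes 0..3
  std::vector<double> x, y, l, a, b;
  std::vector<int> life, repsteps, partner;
  std::vector<unsigned char> state;
  std::vector<unsigned char> alive;
  size_t size() const { return seq.size(); }
};

inline double u01() { return unif_rand(); }          // in (0, 1)
inline double u_pos() { return 1.0 - unif_rand(); }  // in (0, 1]

void shuffle_idx(std::vector<int>& v) {
  for (int i = (int)v.size() - 1; i > 0; --i) {
    int j = (int)(u01() * (i + 1));
    if (j > i) j = i;
    std::swap(v[i], v[j]);
  }
}

int action_steps(double k, double dt) {
  if (!R_FINITE(k)) return 1;
  double t = -std::log(u_pos()) / k;
  double s = std::floor(t / dt) + 1.0;
  if (s > LIFE_FOREVER) return LIFE_FOREVER;
  return (int)s;
}

struct Derive {
  const Params& P;
  std::unordered_map<std::string, double> lcache;
  explicit Derive(const Params& p) : P(p) {}

  double l_of(const std::string& s) {
    std::unordered_map<std::string, double>::iterator it = lcache.find(s);
    if (it != lcache.end()) return it->second;
    std::vector<int> v(s.begin(), s.end());
    int np = nussinov_count(v, P.min_loop, P.wobble);
    double l = 2.0 * np / (double)s.size();
    if (lcache.size() > (1u << 21)) lcache.clear();
    lcache[s] = l;
    return l;
  }
  double a_of(const std::string& s) {
    int m = 0;
    size_t n = std::min(P.motif.size(), s.size());
    for (size_t i = 0; i < n; ++i)
      if ((int)s[i] == P.motif[i]) ++m;
    if (m < P.match_threshold) return 0.0;
    return 1.0 - std::exp(-P.rate_per_match * m * P.dt);
  }
  double b_of(const std::string& s) {
    double b = P.d;
    for (size_t i = 0; i + 1 < s.size(); ++i)
      b += P.hyd[(int)s[i]][(int)s[i + 1]];
    return b;
  }
};

bool mutate_seq(std::string& s, double mu) {
  if (mu <= 0.0) return false;
  bool changed = false;
  for (size_t i = 0; i < s.size(); ++i) {
    if (u01() < mu) {
      int shift = 1 + (int)(u01() * 3.0);
      if (shift > 3) shift = 3;
      s[i] = (char)(((int)s[i] + shift) % 4);
      changed = true;
    }
  }
  return changed;
}

inline double wrapc(double v, double size) {
  v -= size * std::floor(v / size);
  if (v >= size) v = 0.0;  // guard against floating rounding at the seam
  return v;
}

inline double tdist2(double x1, double y1, double x2, double y2,
                     double sx, double sy) {
  double dx = std::fabs(x1 - x2); if (dx > sx - dx) dx = sx - dx;
  double dy = std::fabs(y1 - y2); if (dy > sy - dy) dy = sy - dy;
  return dx * dx + dy * dy;
}

struct Grid {
  int nx, ny;
  double cx, cy, sx, sy;
  bool brute;
  std::vector<std::vector<int> > cells;

  void build(const Pop& pop, const Params& P, size_t limit) {
    sx = P.sizeX; sy = P.sizeY;
    nx = std::max(1, (int)std::floor(P.sizeX / P.radius));
    ny = std::max(1, (int)std::floor(P.sizeY / P.radius));
    brute = (nx < 3 || ny < 3);
    cx = P.sizeX / nx; cy = P.sizeY / ny;
    cells.assign((size_t)nx * ny, std::vector<int>());
    for (size_t i = 0; i < limit; ++i) {
      if (!pop.alive[i]) continue;
      if (brute) { cells[0].push_back((int)i); continue; }
      int a = (int)(pop.x[i] / cx); if (a >= nx) a = nx - 1;
      int b = (int)(pop.y[i] / cy); if (b >= ny) b = ny - 1;
      cells[(size_t)a * ny + b].push_back((int)i);
    }
  }

  // all live agents (any state) strictly within radius, excluding i
  void query(const Pop& pop, int i, double radius,
             std::vector<int>& out) const {
    out.clear();
    const double r2 = radius * radius;
    if (brute) {
      const std::vector<int>& all = cells[0];
      for (size_t t = 0; t < all.size(); ++t) {
        int j = all[t];
        if (j != i && pop.alive[j] &&
            tdist2(pop.x[i], pop.y[i], pop.x[j], pop.y[j], sx, sy) < r2)
          out.push_back(j);
      }
      return;
    }
    int a0 = (int)(pop.x[i] / cx); if (a0 >= nx) a0 = nx - 1;
    int b0 = (int)(pop.y[i] / cy); if (b0 >= ny) b0 = ny - 1;
    for (int da = -1; da <= 1; ++da) {
      int a = (a0 + da + nx) % nx;
      for (int db = -1; db <= 1; ++db) {
        int b = (b0 + db + ny) % ny;
        const std::vector<int>& bucket = cells[(size_t)a * ny + b];
        for (size_t t = 0; t < bucket.size(); ++t) {
          int j = bucket[t];
          if (j != i && pop.alive[j] &&
              tdist2(pop.x[i], pop.y[i], pop.x[j], pop.y[j], sx, sy) < r2)
            out.push_back(j);
        }
      }
    }
  }
};

struct StatRow {
  int step, n_total, n_repl, n_par, n_cplx, births, decays, removals;
  double ma_r, ml_r, ml_p;
};

StatRow collect_stats(const Pop& pop, int step, int births, int decays,
                      int removals) {
  StatRow r;
  r.step = step; r.births = births; r.decays = decays;
  r.removals = removals;
  r.n_total = 0; r.n_repl = 0; r.n_par = 0; r.n_cplx = 0;
  double sa = 0, slr = 0, slp = 0;
  for (size_t i = 0; i < pop.size(); ++i) {
    if (!pop.alive[i]) continue;
    ++r.n_total;
    if (pop.state[i] == 1) ++r.n_cplx;
    if (pop.a[i] > 0) { ++r.n_repl; sa += pop.a[i]; slr += pop.l[i]; }
    else { ++r.n_par; slp += pop.l[i]; }
  }
  r.ma_r = r.n_repl ? sa / r.n_repl : NA_REAL;
  r.ml_r = r.n_repl ? slr / r.n_repl : NA_REAL;
  r.ml_p = r.n_par ? slp / r.n_par : NA_REAL;
  return r;
}

void compact(Pop& pop) {
  size_t n = pop.size();
  std::vector<int> remap(n, -1);
  size_t w = 0;
  for (size_t i = 0; i < n; ++i) {
    if (!pop.alive[i]) continue;
    remap[i] = (int)w;
    if (w != i) {
      pop.seq[w] = pop.seq[i];
      pop.x[w] = pop.x[i]; pop.y[w] = pop.y[i];
      pop.l[w] = pop.l[i]; pop.a[w] = pop.a[i]; pop.b[w] = pop.b[i];
      pop.life[w] = pop.life[i]; pop.repsteps[w] = pop.repsteps[i];
      pop.partner[w] = pop.partner[i]; pop.state[w] = pop.state[i];
    }
    ++w;
  }
  pop.seq.resize(w); pop.x.resize(w); pop.y.resize(w);
  pop.l.resize(w); pop.a.resize(w); pop.b.resize(w);
  pop.life.resize(w); pop.repsteps.resize(w); pop.partner.resize(w);
  pop.state.resize(w);
  pop.alive.assign(w, 1);
  for (size_t i = 0; i < w; ++i)
    if (pop.partner[i] >= 0) pop.partner[i] = remap[pop.partner[i]];
}

void append_agent(Pop& pop, const std::string& s, double x, double y,
                  double l, double a, double b, int life) {
  pop.seq.push_back(s);
  pop.x.push_back(x); pop.y.push_back(y);
  pop.l.push_back(l); pop.a.push_back(a); pop.b.push_back(b);
  pop.life.push_back(life);
  pop.repsteps.push_back(0);
  pop.partner.push_back(-1);
  pop.state.push_back(0);
  pop.alive.push_back(1);
}

}  // namespace

// [[Rcpp::export]]
List sim_run_cpp(CharacterVector seqs, NumericVector x0, NumericVector y0,
                 List par) {
  Params P;
  P.sizeX = as<double>(par["sizeX"]); P.sizeY = as<double>(par["sizeY"]);
  P.radius = as<double>(par["int_radius"]);
  P.dt = as<double>(par["dt"]); P.D = as<double>(par["D"]);
  P.d = as<double>(par["d"]); P.seq_mut = as<double>(par["seq_mut"]);
  P.neigh = as<int>(par["neigh"]);
  P.K = as<double>(par["K"]);
  P.min_loop = as<int>(par["min_loop"]);
  P.wobble = as<bool>(par["allow_wobble"]);
  IntegerVector mot = par["motif"];
  P.motif.assign(mot.begin(), mot.end());
  P.match_threshold = as<int>(par["match_threshold"]);
  P.rate_per_match = as<double>(par["rate_per_match"]);
  NumericMatrix hyd = par["hyd"];
  for (int i = 0; i < 4; ++i)
    for (int j = 0; j < 4; ++j)
      P.hyd[i][j] = hyd(i, j);
  P.max_steps = as<int>(par["max_steps"]);
  P.seq_length = as<int>(par["seq_length"]);

  Derive derive(P);
  Pop pop;
  const int n0 = seqs.size();
  for (int i = 0; i < n0; ++i) {
    std::string raw = as<std::string>(seqs[i]);
    std::string s(raw.size(), 0);
    for (size_t t = 0; t < raw.size(); ++t) {
      switch (raw[t]) {
        case 'A': s[t] = 0; break;
        case 'C': s[t] = 1; break;
        case 'G': s[t] = 2; break;
        case 'U': s[t] = 3; break;
        default: stop("sequence symbol outside {A,C,G,U}");
      }
    }
    double l = derive.l_of(s), a = derive.a_of(s), b = derive.b_of(s);
    int life = b > 0 ? action_steps(b, P.dt) : LIFE_FOREVER;
    append_agent(pop, s, wrapc(x0[i], P.sizeX), wrapc(y0[i], P.sizeY),
                 l, a, b, life);
  }

  std::vector<StatRow> stats;
  stats.push_back(collect_stats(pop, 0, 0, 0, 0));

  Grid grid;
  std::vector<int> order, nb;
  int steps_run = 0;

  for (int step = 1; step <= P.max_steps; ++step) {
    int births = 0, decays = 0, removals = 0;

    // --- phase 1: decay, replication countdown, diffusion ---
    const int nA = (int)pop.size();
    order.resize(nA);
    for (int i = 0; i < nA; ++i) order[i] = i;
    shuffle_idx(order);
    for (int t = 0; t < nA; ++t) {
      const int i = order[t];
      if (!pop.alive[i]) continue;
      if (pop.state[i] == 1) {
        // enzyme drives the complex countdown once per complex per step
        if (--pop.repsteps[i] == 0) {
          const int tpl = pop.partner[i];
          std::string child = pop.seq[tpl];
          const bool changed = mutate_seq(child, P.seq_mut);
          // an exact copy inherits the template's derived parameters
          double l, a, b;
          if (changed) {
            l = derive.l_of(child); a = derive.a_of(child);
            b = derive.b_of(child);
          } else {
            l = pop.l[tpl]; a = pop.a[tpl]; b = pop.b[tpl];
          }
          int life = b > 0 ? action_steps(b, P.dt) : LIFE_FOREVER;
          append_agent(pop, child, pop.x[tpl], pop.y[tpl], l, a, b, life);
          ++births;
          // dissociation: both members resume aging and diffusion
          pop.state[i] = 0; pop.state[tpl] = 0;
          pop.partner[i] = -1; pop.partner[tpl] = -1;
        }
      } else if (pop.state[i] == 0) {
        if (--pop.life[i] == 0) {
          pop.alive[i] = 0;
          ++decays;
        } else {
          double w = std::sqrt(6.0 * P.dt * P.D * u01());
          double th = 2.0 * M_PI * u01();
          pop.x[i] = wrapc(pop.x[i] + w * std::cos(th), P.sizeX);
          pop.y[i] = wrapc(pop.y[i] + w * std::sin(th), P.sizeY);
        }
      }
      // templates (state 2) wait: no aging, no diffusion
    }

    // --- phase 2: crowding removal and complex formation ---
    const int nB = (int)pop.size();  // includes this step's offspring
    grid.build(pop, P, pop.size());
    order.clear();
    for (int i = 0; i < nB; ++i)
      if (pop.alive[i] && pop.state[i] == 0) order.push_back(i);
    shuffle_idx(order);
    for (size_t t = 0; t < order.size(); ++t) {
      const int i = order[t];
      if (!pop.alive[i] || pop.state[i] != 0) continue;
      grid.query(pop, i, P.radius, nb);
      shuffle_idx(nb);
      if ((int)nb.size() > P.neigh) {
        pop.alive[i] = 0;
        ++removals;
        continue;
      }
      for (size_t q = 0; q < nb.size(); ++q) {
        const int j = nb[q];
        if (!pop.alive[j] || pop.state[j] != 0) continue;
        const double pr = pop.a[i] * pop.l[i] * (1.0 - pop.l[j]);
        const double p = u01();
        if (p < pr) {
          pop.state[i] = 1; pop.state[j] = 2;
          pop.partner[i] = j; pop.partner[j] = i;
          pop.repsteps[i] = action_steps(P.K, P.dt);
          break;
        }
      }
    }

    compact(pop);
    stats.push_back(collect_stats(pop, step, births, decays, removals));
    steps_run = step;
    if (pop.size() == 0) break;
    if (step % 256 == 0) Rcpp::checkUserInterrupt();
  }

  // assemble outputs
  const int ns = (int)stats.size();
  IntegerVector st(ns), ntot(ns), nr(ns), np(ns), nc(ns), bi(ns), de(ns),
      rm(ns);
  NumericVector mar(ns), mlr(ns), mlp(ns);
  for (int i = 0; i < ns; ++i) {
    st[i] = stats[i].step; ntot[i] = stats[i].n_total;
    nr[i] = stats[i].n_repl; np[i] = stats[i].n_par;
    nc[i] = stats[i].n_cplx;
    mar[i] = stats[i].ma_r; mlr[i] = stats[i].ml_r; mlp[i] = stats[i].ml_p;
    bi[i] = stats[i].births; de[i] = stats[i].decays;
    rm[i] = stats[i].removals;
  }
  DataFrame statdf = DataFrame::create(
      _["step"] = st, _["n_total"] = ntot, _["n_replicases"] = nr,
      _["n_parasites"] = np, _["n_complexes"] = nc,
      _["mean_a_replicases"] = mar, _["mean_l_replicases"] = mlr,
      _["mean_l_parasites"] = mlp, _["births"] = bi, _["decays"] = de,
      _["removals"] = rm);

  const int nf = (int)pop.size();
  CharacterVector fseq(nf), fstate(nf);
  NumericVector fx(nf), fy(nf), fl(nf), fa(nf), fb(nf);
  const char* letters = "ACGU";
  const char* states[3] = {"free", "enzyme", "template"};
  for (int i = 0; i < nf; ++i) {
    std::string s(pop.seq[i].size(), 'A');
    for (size_t t = 0; t < s.size(); ++t)
      s[t] = letters[(int)pop.seq[i][t]];
    fseq[i] = s;
    fx[i] = pop.x[i]; fy[i] = pop.y[i];
    fl[i] = pop.l[i]; fa[i] = pop.a[i]; fb[i] = pop.b[i];
    fstate[i] = states[pop.state[i]];
  }
  DataFrame popdf = DataFrame::create(
      _["sequence"] = fseq, _["x"] = fx, _["y"] = fy, _["l"] = fl,
      _["a"] = fa, _["b"] = fb, _["state"] = fstate,
      _["stringsAsFactors"] = false);

  return List::create(_["stats"] = statdf, _["population"] = popdf,
                      _["steps_run"] = steps_run);
}
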