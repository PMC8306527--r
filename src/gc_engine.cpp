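// Stochastic well-mixed agent-based simulation of a single germinal center.
//
// B-cell agents divide with somatic hypermutation in a 4D shape-space
// lattice, collect antigen portions from a shared FDC pool, and compete for
// polarized Tfh help. Spatial encounters of the underlying lattice model are
// reduced to per-timestep contact opportunities: each collecting cell makes
// fdc_encounter_rate*dt binding attempts per step, and each collector is
// each collector samples one of n_tfh Tfh cells per step (B cells interact
// with several neighboring Tfh over a contact), and each Tfh polarizes to
// the sampled cell with the most collected antigen that step.
//
// All randomness goes through R's RNG so that runs are reproducible from
// set.seed() on the R side. Antigen portions are integer throughout; the
// pool, the portions held by live cells, and the portions carried away by
// plasma output and dead cells form an exact conservation ledger.

#include <Rcpp.h>
#include <vector>
#include <cmath>
using namespace Rcpp;

namespace {

const double TOL = 1e-9;

enum CellState { DIVIDING = 0, COLLECTING = 1, TFH = 2, DEAD = 3 };
enum Program { FOUNDER = 0, SELECTED = 1 };

struct Cell {
  signed char pos[4];
  signed char state;
  signed char program;
  signed char epi;      // epitope of the last collected portion, -1 if none
  signed char fresh;    // entered Tfh contact this step; starts next step
  short divs;           // divisions remaining in current program
  int antigen;          // portions currently held
  double clock;         // time remaining in current state (h)
  double pol;           // accumulated polarized-Tfh time (h)
  int tfh;              // contact-group index while in TFH state
};

struct Engine {
  // parameters
  double dt, duration, influx_rate, influx_duration;
  int founder_divisions, n_fdc, n_tfh, max_divisions;
  double mutation_prob, collection_window, tfh_contact_duration;
  double polarization_threshold, asymmetric_fraction, recycling_prob;
  double feedback_strength, feedback_K, gamma;
  double fdc_encounter_rate, availability_K, availability_hill;
  double fdc_decay_rate, tfh_signal_prob, cycle_mean, cycle_cv;
  double gc_capacity;
  double record_every;
  int lo, hi; // lattice bounds

  int n_epi;
  std::vector<signed char> optima; // n_epi x 4
  std::vector<long long> rem;      // portions remaining per epitope
  long long total_rem;
  std::vector<double> mask;        // masked fraction per epitope
  std::vector<double> pw;          // affinity-weighted plasma per epitope
  std::vector<long long> plasma_epi;

  std::vector<double> aff_table;   // affinity by squared distance
  std::vector<Cell> cells;
  std::vector<std::vector<int> > buckets;

  long long cum_plasma, antigen_output, antigen_dead, antigen_decayed;
  long long founders_in;

  double gshape, gscale;

  double cycle_time() { return R::rgamma(gshape, gscale); }

  double aff(const Cell& c, int e) const {
    int d2 = 0;
    for (int k = 0; k < 4; ++k) {
      int d = (int)c.pos[k] - (int)optima[4 * e + k];
      d2 += d * d;
    }
    return aff_table[d2];
  }

  void mutate(Cell& c) {
    if (unif_rand() >= mutation_prob) return;
    for (;;) {
      int axis = (int)(unif_rand() * 4.0);
      if (axis > 3) axis = 3;
      int step = (unif_rand() < 0.5) ? -1 : 1;
      int v = (int)c.pos[axis] + step;
      if (v >= lo && v <= hi) { c.pos[axis] = (signed char)v; return; }
    }
  }

  int divisions_for(int antigen) const {
    int d = 1 + (int)std::floor(std::log2(1.0 + (double)antigen));
    return d > max_divisions ? max_divisions : d;
  }

  void start_collecting(Cell& c) {
    c.state = COLLECTING;
    c.clock = collection_window;
  }

  // Fate of a daughter with no divisions left.
  // Returns true if the cell stays in the population.
  bool resolve_terminal(Cell& c) {
    if (c.program == FOUNDER) {           // founder expansion done: enter LZ
      start_collecting(c);
      return true;
    }
    if (c.antigen > 0) {                  // antigen-retaining: plasma output
      ++cum_plasma;
      antigen_output += c.antigen;
      int e = c.epi >= 0 ? c.epi : 0;
      ++plasma_epi[e];
      pw[e] += aff(c, e);
      return false;
    }
    if (unif_rand() < recycling_prob) {   // recycle to the light zone
      start_collecting(c);
      return true;
    }
    c.state = DEAD;                       // exit without output
    return false;
  }

  void divide(int i) {
    Cell parent = cells[i];
    int a1, a2;
    if (unif_rand() < asymmetric_fraction) {
      a1 = parent.antigen; a2 = 0;        // one daughter retains all antigen
    } else {
      a1 = (parent.antigen + 1) / 2; a2 = parent.antigen / 2;
    }
    short nd = (short)(parent.divs - 1);

    Cell d1 = parent;
    d1.divs = nd; d1.antigen = a1; d1.pol = 0.0;
    mutate(d1);
    Cell d2 = parent;
    d2.divs = nd; d2.antigen = a2; d2.pol = 0.0;
    mutate(d2);

    bool keep1, keep2;
    if (nd <= 0) {
      keep1 = resolve_terminal(d1);
      keep2 = resolve_terminal(d2);
    } else {
      d1.state = DIVIDING; d1.clock = cycle_time(); keep1 = true;
      d2.state = DIVIDING; d2.clock = cycle_time(); keep2 = true;
    }
    if (keep1) {
      cells[i] = d1;
      if (keep2) cells.push_back(d2);
    } else if (keep2) {
      cells[i] = d2;
    } else {
      cells[i].state = DEAD;
      cells[i].antigen = 0;  // terminal fates already accounted the antigen
    }
  }

  // Expected attempts per step may be fractional: the integer part is made
  // always, the remainder with the matching probability.
  void attempt_collection(Cell& c, double att) {
    int n_att = (int)att;
    if (unif_rand() < att - n_att) ++n_att;
    for (int k = 0; k < n_att; ++k) {
      if (total_rem <= 0) return;
      // epitope chosen proportional to its remaining portions
      double u = unif_rand() * (double)total_rem;
      int e = 0;
      double acc = 0.0;
      for (; e < n_epi - 1; ++e) {
        acc += (double)rem[e];
        if (u < acc) break;
      }
      if (rem[e] <= 0) continue;
      double per_fdc = (double)rem[e] / (double)n_fdc;
      double avail;
      if (availability_K <= 0.0) {
        avail = 1.0;
      } else {
        double ah = std::pow(per_fdc, availability_hill);
        double kh = std::pow(availability_K, availability_hill);
        avail = ah / (ah + kh);
      }
      double p = aff(c, e) * avail * (1.0 - feedback_strength * mask[e]);
      if (unif_rand() < p) {
        --rem[e];
        --total_rem;
        ++c.antigen;
        c.epi = (signed char)e;
      }
    }
  }
};

} // namespace

// [[Rcpp::export(name = ".run_gc_cpp")]]
List run_gc_cpp(List params, IntegerMatrix optima, NumericVector fractions,
                IntegerMatrix founder_pool, IntegerVector bounds) {
  Engine E;
  E.dt = as<double>(params["dt"]);
  E.duration = as<double>(params["duration"]);
  E.influx_rate = as<double>(params["influx_rate"]);
  E.influx_duration = as<double>(params["influx_duration"]);
  E.founder_divisions = as<int>(params["founder_divisions"]);
  E.n_fdc = as<int>(params["n_fdc"]);
  E.n_tfh = as<int>(params["n_tfh"]);
  E.max_divisions = as<int>(params["max_divisions"]);
  E.mutation_prob = as<double>(params["mutation_prob"]);
  E.collection_window = as<double>(params["collection_window"]);
  E.tfh_contact_duration = as<double>(params["tfh_contact_duration"]);
  E.polarization_threshold = as<double>(params["polarization_threshold"]);
  E.asymmetric_fraction = as<double>(params["asymmetric_fraction"]);
  E.recycling_prob = as<double>(params["recycling_prob"]);
  E.feedback_strength = as<double>(params["feedback_strength"]);
  E.feedback_K = as<double>(params["feedback_K"]);
  E.gamma = as<double>(params["gamma"]);
  E.fdc_encounter_rate = as<double>(params["fdc_encounter_rate"]);
  E.availability_K = as<double>(params["availability_K"]);
  E.availability_hill = as<double>(params["availability_hill"]);
  E.fdc_decay_rate = as<double>(params["fdc_decay_rate"]);
  E.tfh_signal_prob = as<double>(params["tfh_signal_prob"]);
  E.gc_capacity = as<double>(params["gc_capacity"]);
  E.cycle_mean = as<double>(params["cycle_mean"]);
  E.cycle_cv = as<double>(params["cycle_cv"]);
  E.record_every = as<double>(params["record_every"]);
  double antigen_per_fdc = as<double>(params["antigen_per_fdc"]);
  E.lo = bounds[0];
  E.hi = bounds[1];

  E.gshape = 1.0 / (E.cycle_cv * E.cycle_cv);
  E.gscale = E.cycle_mean / E.gshape;

  E.n_epi = optima.nrow();
  E.optima.resize(4 * E.n_epi);
  for (int e = 0; e < E.n_epi; ++e)
    for (int k = 0; k < 4; ++k)
      E.optima[4 * e + k] = (signed char)optima(e, k);

  // per-epitope pools partition the total initial portions
  E.rem.resize(E.n_epi);
  E.total_rem = 0;
  double total0 = antigen_per_fdc * (double)E.n_fdc;
  for (int e = 0; e < E.n_epi; ++e) {
    E.rem[e] = (long long)std::llround(total0 * fractions[e]);
    E.total_rem += E.rem[e];
  }
  long long initial_total = E.total_rem;

  E.mask.assign(E.n_epi, 0.0);
  E.pw.assign(E.n_epi, 0.0);
  E.plasma_epi.assign(E.n_epi, 0);

  int span = E.hi - E.lo;
  int d2max = 4 * span * span;
  E.aff_table.resize(d2max + 1);
  for (int d2 = 0; d2 <= d2max; ++d2)
    E.aff_table[d2] = std::exp(-(double)d2 / (E.gamma * E.gamma));

  E.cum_plasma = 0;
  E.antigen_output = 0;
  E.antigen_dead = 0;
  E.antigen_decayed = 0;
  E.founders_in = 0;
  E.buckets.assign(E.n_tfh, std::vector<int>());
  E.cells.reserve(4096);

  int n_steps = (int)std::llround(E.duration / E.dt);
  int rec_steps = std::max(1, (int)std::llround(E.record_every / E.dt));
  double n_att = E.fdc_encounter_rate * E.dt;
  int next_founder = 0;

  int n_rec = n_steps / rec_steps + 1;
  NumericVector r_time(n_rec), r_live(n_rec), r_plasma(n_rec);
  NumericVector r_rem(n_rec), r_held(n_rec), r_out(n_rec), r_dead(n_rec);
  NumericVector r_dec(n_rec);
  int ir = 0;
  // record t = 0 (empty GC)
  r_time[ir] = 0.0; r_live[ir] = 0; r_plasma[ir] = 0;
  r_rem[ir] = (double)E.total_rem; r_held[ir] = 0; r_out[ir] = 0;
  r_dead[ir] = 0; r_dec[ir] = 0;
  ++ir;

  double p_dec = 1.0 - std::exp(-E.fdc_decay_rate * E.dt);

  for (int step = 0; step < n_steps; ++step) {
    double t = step * E.dt;

    // clearance of FDC-held immune complexes, independent of consumption
    if (p_dec > 0 && E.total_rem > 0) {
      for (int e = 0; e < E.n_epi; ++e) {
        if (E.rem[e] <= 0) continue;
        long long lost = (long long)R::rbinom((double)E.rem[e], p_dec);
        E.rem[e] -= lost;
        E.total_rem -= lost;
        E.antigen_decayed += lost;
      }
    }

    // founder influx: Poisson arrivals while t < influx_duration
    if (t < E.influx_duration - TOL && E.influx_rate > 0) {
      int k = (int)R::rpois(E.influx_rate * E.dt);
      for (int j = 0; j < k; ++j) {
        if (next_founder >= founder_pool.nrow())
          stop("founder pool exhausted; enlarge the pre-sampled pool");
        Cell c;
        for (int ax = 0; ax < 4; ++ax)
          c.pos[ax] = (signed char)founder_pool(next_founder, ax);
        ++next_founder;
        ++E.founders_in;
        c.program = FOUNDER;
        c.epi = -1;
        c.fresh = 0;
        c.antigen = 0;
        c.pol = 0.0;
        c.tfh = -1;
        if (E.founder_divisions > 0) {
          c.state = DIVIDING;
          c.divs = (short)E.founder_divisions;
          c.clock = E.cycle_time();
        } else {
          c.divs = 0;
          E.start_collecting(c);
        }
        E.cells.push_back(c);
      }
    }

    // antibody feedback: epitope masking from affinity-weighted output
    if (E.feedback_strength > 0) {
      for (int e = 0; e < E.n_epi; ++e)
        E.mask[e] = E.pw[e] / (E.pw[e] + E.feedback_K);
    }

    // phase A: division clocks, antigen collection, state transitions
    size_t n0 = E.cells.size();
    for (size_t i = 0; i < n0; ++i) {
      Cell& c = E.cells[i];
      switch (c.state) {
      case DIVIDING:
        c.clock -= E.dt;
        if (c.clock <= TOL) E.divide((int)i);
        break;
      case COLLECTING: {
        c.clock -= E.dt;
        E.attempt_collection(c, n_att);
        if (c.clock <= TOL) {
          if (c.antigen > 0) {           // proceed to seek Tfh help
            c.state = TFH;
            c.clock = E.tfh_contact_duration;
            c.pol = 0.0;
            c.fresh = 1;
            c.tfh = -1;
          } else {                        // failed collection: apoptosis
            c.state = DEAD;
          }
        }
        break;
      }
      case TFH:
        if (!c.fresh) c.clock -= E.dt;
        break;
      default:
        break;
      }
    }

    // phase B: Tfh polarization and contact expiry
    for (int b = 0; b < E.n_tfh; ++b) E.buckets[b].clear();
    for (size_t i = 0; i < E.cells.size(); ++i) {
      Cell& c = E.cells[i];
      if (c.state == TFH) {
        if (c.fresh) { c.fresh = 0; continue; } // contact starts next step
        int b = (int)(unif_rand() * (double)E.n_tfh);
        if (b >= E.n_tfh) b = E.n_tfh - 1;
        E.buckets[b].push_back((int)i);
      }
    }
    for (int b = 0; b < E.n_tfh; ++b) {
      std::vector<int>& grp = E.buckets[b];
      if (grp.empty()) continue;
      // Tfh polarizes to the member with the most antigen; ties random
      int best = grp[0];
      int n_tie = 1;
      for (size_t j = 1; j < grp.size(); ++j) {
        int i = grp[j];
        if (E.cells[i].antigen > E.cells[best].antigen) {
          best = i; n_tie = 1;
        } else if (E.cells[i].antigen == E.cells[best].antigen) {
          ++n_tie;
          if (unif_rand() < 1.0 / (double)n_tie) best = i;
        }
      }
      // engagement is stochastic: even an uncontested B cell receives a
      // productive polarized signal only part of the time
      if (unif_rand() < E.tfh_signal_prob) E.cells[best].pol += E.dt;
    }
    for (size_t i = 0; i < E.cells.size(); ++i) {
      Cell& c = E.cells[i];
      if (c.state != TFH || c.clock > TOL) continue;
      if (c.pol >= E.polarization_threshold - TOL) {
        c.state = DIVIDING;               // selected: divide per antigen
        c.program = SELECTED;
        c.divs = (short)E.divisions_for(c.antigen);
        c.clock = E.cycle_time();
      } else {
        c.state = DEAD;                   // insufficient Tfh signal
      }
    }

    // phase C: remove dead cells, antigen leaving with them is tallied
    size_t w = 0;
    for (size_t i = 0; i < E.cells.size(); ++i) {
      if (E.cells[i].state == DEAD) {
        E.antigen_dead += E.cells[i].antigen;
      } else {
        if (w != i) E.cells[w] = E.cells[i];
        ++w;
      }
    }
    E.cells.resize(w);

    // spatial carrying capacity: the GC volume bounds how many B cells fit;
    // above it, survival is density-dependent (binomial thinning)
    if (E.gc_capacity > 0 && (double)E.cells.size() > E.gc_capacity) {
      double keep_p = E.gc_capacity / (double)E.cells.size();
      size_t v = 0;
      for (size_t i = 0; i < E.cells.size(); ++i) {
        if (unif_rand() < keep_p) {
          if (v != i) E.cells[v] = E.cells[i];
          ++v;
        } else {
          E.antigen_dead += E.cells[i].antigen;
        }
      }
      E.cells.resize(v);
    }

    if (E.cells.size() > 2000000)
      stop("population exceeded 2e6 cells; parameters imply runaway growth");

    if ((step + 1) % rec_steps == 0) {
      long long held = 0;
      for (size_t i = 0; i < E.cells.size(); ++i) held += E.cells[i].antigen;
      r_time[ir] = (step + 1) * E.dt;
      r_live[ir] = (double)E.cells.size();
      r_plasma[ir] = (double)E.cum_plasma;
      r_rem[ir] = (double)E.total_rem;
      r_held[ir] = (double)held;
      r_out[ir] = (double)E.antigen_output;
      r_dead[ir] = (double)E.antigen_dead;
      r_dec[ir] = (double)E.antigen_decayed;
      ++ir;
    }
  }

  NumericVector pe(E.n_epi), mk(E.n_epi);
  for (int e = 0; e < E.n_epi; ++e) {
    pe[e] = (double)E.plasma_epi[e];
    mk[e] = E.mask[e];
  }

  return List::create(
    _["time_h"] = r_time, _["live_cells"] = r_live,
    _["cumulative_plasma"] = r_plasma, _["antigen_remaining"] = r_rem,
    _["antigen_in_cells"] = r_held, _["antigen_output"] = r_out,
    _["antigen_dead"] = r_dead, _["antigen_decayed"] = r_dec,
    _["plasma_by_epitope"] = pe,
    _["masked_fraction"] = mk, _["initial_antigen"] = (double)initial_total,
    _["total_founders"] = (double)E.founders_in);
}
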