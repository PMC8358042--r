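// Gillespie direct-method core with just-in-time reaction enumeration.
//
// Species are linear DNA complexes encoded as integer token sequences.
// Reaction channels are instantiated lazily: when a species first acquires
// positive copy number it is matched (by exposed-site pattern) against every
// other live species, so the unbounded polymer state space is never
// enumerated up front.  Propensities are cached per channel and summed in
// blocks so channel selection stays cheap as the network grows.

#include <Rcpp.h>
#include <unordered_map>
#include <string>
#include <vector>
#include <cmath>

using namespace Rcpp;

namespace {

// token ids, fixed to match TOKENS in R: s p X Y w r q k z
enum Tok { TS = 1, TP = 2, TX = 3, TY = 4, TW = 5, TR = 6, TQ = 7, TK = 8, TZ = 9 };

inline bool is_signal(int t) { return t == TX || t == TY || t == TW; }

// exposed-site kinds
enum Site { SITE_NONE = 0, SITE_ALPHA = 1, SITE_BETA = 2, SITE_LINKER = 3 };

// rule ids (decoded to labels on the R side)
enum Rule {
  RULE_R1 = 1,   // elongation by push at an alpha_open end
  RULE_R2 = 2,   // elongation by signal at a beta_open end
  RULE_R3 = 3,   // read displaces terminal signal
  RULE_R3C = 32, // read caps a terminal start
  RULE_R3F = 33, // read hybridises a free signal monomer
  RULE_R4 = 4,   // pop displaces terminal push
  RULE_R4F = 43, // pop hybridises a free push monomer
  RULE_R5A = 51, // start(-headed complex) nucleates on bead linker
  RULE_R5B = 52, // releaser ejects a tethered stack
  RULE_R5Z = 53  // releaser caps an unused linker
};

struct Species {
  std::vector<int> toks;
  bool tethered;
  bool inert;
  int tail;       // site exposed at the growing (3') end
  int head_binds; // site the head of a free complex attaches to
};

struct Opts {
  bool rule_on[6];       // R1..R5 master switches (index 1..5)
  bool cap_start;        // r capping of a terminal s
  bool r_free_signal;    // r + free signal monomer -> duplex
  bool q_free_push;      // q + free p monomer -> duplex
  bool chain_nucleation; // s-headed complexes (not just s) bind linker
};

Species make_species(const std::vector<int>& toks) {
  Species sp;
  sp.toks = toks;
  sp.tethered = toks.front() == TK;
  const int last = toks.back();
  sp.inert = (last == TR || last == TQ || last == TZ);
  if (sp.inert)
    sp.tail = SITE_NONE;
  else if (toks.size() == 1 && last == TK)
    sp.tail = SITE_LINKER;
  else if (last == TS || is_signal(last))
    sp.tail = SITE_ALPHA;
  else if (last == TP)
    sp.tail = SITE_BETA;
  else
    sp.tail = SITE_NONE;
  const int first = toks.front();
  if (sp.tethered)
    sp.head_binds = SITE_NONE;
  else if (first == TP)
    sp.head_binds = SITE_ALPHA;
  else if (is_signal(first))
    sp.head_binds = SITE_BETA;
  else if (first == TS)
    sp.head_binds = SITE_LINKER;
  else
    sp.head_binds = SITE_NONE;
  return sp;
}

std::string tok_key(const std::vector<int>& toks) {
  std::string k;
  k.reserve(toks.size());
  for (int t : toks) k.push_back(static_cast<char>('0' + t));
  return k;
}

class Network {
public:
  std::vector<Species> sp;
  std::unordered_map<std::string, int> index;
  std::vector<double> n; // copy numbers
  std::vector<char> introduced;
  std::vector<int> intro_list;
  std::vector<std::vector<int>> touch; // species -> channels using it as reactant

  // channels (structure-of-arrays)
  std::vector<int> ch_i, ch_j, ch_rule, ch_p1, ch_p2; // p2 = -1 if single product
  std::vector<double> ch_c;    // stochastic rate constant k/(V*NA)
  std::vector<double> ch_rate; // macroscopic rate constant (M^-1 s^-1)
  std::vector<double> a;       // cached propensities
  std::vector<double> bsum;    // block partial sums of a

  double kA, kBC, inv_vna;
  Opts opt;
  static const int BS = 64;

  int register_species(const std::vector<int>& toks) {
    const std::string key = tok_key(toks);
    auto it = index.find(key);
    if (it != index.end()) return it->second;
    const int id = static_cast<int>(sp.size());
    sp.push_back(make_species(toks));
    index.emplace(key, id);
    n.push_back(0.0);
    introduced.push_back(0);
    touch.push_back(std::vector<int>());
    return id;
  }

  double prop(int c) const {
    const int i = ch_i[c], j = ch_j[c];
    if (i == j) return ch_c[c] * n[i] * (n[i] - 1.0) * 0.5;
    return ch_c[c] * n[i] * n[j];
  }

  void set_a(int c, double v) {
    const int b = c / BS;
    bsum[b] += v - a[c];
    a[c] = v;
  }

  void add_channel(int i, int j, double rate, int rule, int p1, int p2) {
    const int c = static_cast<int>(ch_i.size());
    ch_i.push_back(i);
    ch_j.push_back(j);
    ch_rule.push_back(rule);
    ch_p1.push_back(p1);
    ch_p2.push_back(p2);
    ch_rate.push_back(rate);
    ch_c.push_back(rate * inv_vna);
    touch[i].push_back(c);
    if (j != i) touch[j].push_back(c);
    a.push_back(0.0);
    if (static_cast<int>(bsum.size()) <= c / BS) bsum.resize(c / BS + 1, 0.0);
    set_a(c, prop(c));
  }

  // instantiate every rule matching ordered pair (target, attacker)
  void gen_pair(int ti, int aj) {
    // copies, not references: register_species() may reallocate sp
    const Species T = sp[ti];
    const Species A = sp[aj];
    if (A.tethered) return; // the attacking partner must be in solution

    // joins: attacker head matches target's exposed end; inert duplexes and
    // capped complexes take part in nothing even when duplex-headed
    if (!T.inert && !A.inert && A.head_binds != SITE_NONE && T.tail == A.head_binds) {
      bool ok = true;
      int rule = 0;
      double rate = 0.0;
      if (T.tail == SITE_ALPHA) {
        rule = RULE_R1; rate = kA; ok = opt.rule_on[1];
      } else if (T.tail == SITE_BETA) {
        rule = RULE_R2; rate = kBC; ok = opt.rule_on[2];
      } else { // linker nucleation
        rule = RULE_R5A; rate = kA;
        ok = opt.rule_on[5] && (A.toks.size() == 1 || opt.chain_nucleation);
      }
      if (ok) {
        std::vector<int> prod(T.toks);
        prod.insert(prod.end(), A.toks.begin(), A.toks.end());
        add_channel(ti, aj, rate, rule, register_species(prod), -1);
      }
    }

    // displacement / capping / release need a monomeric attacker
    if (A.toks.size() != 1) return;
    const int at = A.toks[0];

    if (at == TR && !T.inert && opt.rule_on[3]) {
      const int last = T.toks.back();
      if (is_signal(last)) {
        std::vector<int> dup; dup.push_back(last); dup.push_back(TR);
        if (T.toks.size() == 1) {
          if (opt.r_free_signal)
            add_channel(ti, aj, kA, RULE_R3F, register_species(dup), -1);
        } else {
          std::vector<int> rest(T.toks.begin(), T.toks.end() - 1);
          add_channel(ti, aj, kA, RULE_R3,
                      register_species(rest), register_species(dup));
        }
      } else if (last == TS && opt.cap_start) {
        std::vector<int> capped(T.toks);
        capped.push_back(TR);
        add_channel(ti, aj, kA, RULE_R3C, register_species(capped), -1);
      }
    }

    if (at == TQ && !T.inert && opt.rule_on[4] && T.toks.back() == TP) {
      std::vector<int> dup; dup.push_back(TP); dup.push_back(TQ);
      if (T.toks.size() == 1) {
        if (opt.q_free_push)
          add_channel(ti, aj, kBC, RULE_R4F, register_species(dup), -1);
      } else {
        std::vector<int> rest(T.toks.begin(), T.toks.end() - 1);
        add_channel(ti, aj, kBC, RULE_R4,
                    register_species(rest), register_species(dup));
      }
    }

    if (at == TZ && T.tethered && opt.rule_on[5]) {
      std::vector<int> kz; kz.push_back(TK); kz.push_back(TZ);
      if (T.toks.size() == 1) { // bare linker
        add_channel(ti, aj, kA, RULE_R5Z, register_species(kz), -1);
      } else if (T.toks[1] == TS) { // any tethered stack, capped or not
        std::vector<int> rest(T.toks.begin() + 1, T.toks.end());
        add_channel(ti, aj, kA, RULE_R5B,
                    register_species(kz), register_species(rest));
      }
    }
  }

  void introduce(int idx) {
    if (introduced[idx]) return;
    introduced[idx] = 1;
    const size_t m = intro_list.size();
    for (size_t q = 0; q < m; ++q) {
      const int x = intro_list[q];
      gen_pair(x, idx);
      gen_pair(idx, x);
    }
    gen_pair(idx, idx);
    intro_list.push_back(idx);
  }

  void refresh_species(int s) {
    for (int c : touch[s]) set_a(c, prop(c));
  }

  double total() const {
    double t = 0.0;
    for (double b : bsum) t += b;
    return t;
  }
};

Opts parse_opts(List opts) {
  Opts o;
  LogicalVector rules = opts["rules"]; // length 5, R1..R5
  for (int i = 1; i <= 5; ++i) o.rule_on[i] = rules[i - 1];
  o.cap_start = as<bool>(opts["cap_start"]);
  o.r_free_signal = as<bool>(opts["r_free_signal"]);
  o.q_free_push = as<bool>(opts["q_free_push"]);
  o.chain_nucleation = as<bool>(opts["chain_nucleation"]);
  return o;
}

void seed_network(Network& net, List tokens, NumericVector counts,
                  double kA, double kBC, double volume, List opts) {
  const double NAVO = 6.02214076e23;
  net.kA = kA;
  net.kBC = kBC;
  net.inv_vna = 1.0 / (volume * NAVO);
  net.opt = parse_opts(opts);
  const int ns = tokens.size();
  std::vector<int> ids(ns);
  for (int i = 0; i < ns; ++i) {
    IntegerVector tv = tokens[i];
    std::vector<int> toks(tv.begin(), tv.end());
    const int id = net.register_species(toks);
    if (net.n[id] != 0.0)
      stop("duplicate species in input state");
    net.n[id] = (counts.size() > 0) ? counts[i] : 0.0;
    ids[i] = id;
  }
  for (int id : ids) net.introduce(id);
}

} // namespace

// [[Rcpp::export]]
List ssa_advance_cpp(List tokens, NumericVector counts, double kA, double kBC,
                     double volume, double duration, double max_steps,
                     List opts) {
  Network net;
  seed_network(net, tokens, counts, kA, kBC, volume, opts);

  RNGScope rng;
  double t = 0.0;
  double steps = 0.0;
  const int nb0 = Network::BS;

  while (true) {
    const double tot = net.total();
    if (tot <= 0.0) { t = duration; break; }
    const double u1 = unif_rand();
    const double dt = -std::log(u1) / tot;
    if (t + dt > duration) { t = duration; break; }
    t += dt;

    // select channel: block scan then within-block scan
    double target = unif_rand() * tot;
    int c = -1;
    const int nb = static_cast<int>(net.bsum.size());
    for (int b = 0; b < nb; ++b) {
      if (target < net.bsum[b]) {
        const int lo = b * nb0;
        const int hi = std::min<int>(static_cast<int>(net.a.size()), lo + nb0);
        for (int k = lo; k < hi; ++k) {
          if (target < net.a[k]) { c = k; break; }
          target -= net.a[k];
        }
        if (c < 0) { // numerical slack: take last positive in block
          for (int k = hi - 1; k >= lo; --k)
            if (net.a[k] > 0.0) { c = k; break; }
        }
        break;
      }
      target -= net.bsum[b];
    }
    if (c < 0) { // roundoff fell off the end: take any positive channel
      for (int k = static_cast<int>(net.a.size()) - 1; k >= 0; --k)
        if (net.a[k] > 0.0) { c = k; break; }
      if (c < 0) { t = duration; break; }
    }

    const int i = net.ch_i[c], j = net.ch_j[c];
    const int p1 = net.ch_p1[c], p2 = net.ch_p2[c];
    net.n[i] -= 1.0;
    net.n[j] -= 1.0; // i == j subtracts twice, as required for self-pairs
    net.n[p1] += 1.0;
    if (p2 >= 0) net.n[p2] += 1.0;
    if (!net.introduced[p1]) net.introduce(p1);
    if (p2 >= 0 && !net.introduced[p2]) net.introduce(p2);
    net.refresh_species(i);
    if (j != i) net.refresh_species(j);
    if (p1 != i && p1 != j) net.refresh_species(p1);
    if (p2 >= 0 && p2 != i && p2 != j && p2 != p1) net.refresh_species(p2);

    steps += 1.0;
    if (steps >= max_steps)
      stop("SSA exceeded max_steps (%.0f); increase max_steps or shorten the stage",
           max_steps);
    if (static_cast<long>(steps) % 65536 == 0) {
      Rcpp::checkUserInterrupt();
      // periodic full refresh against float drift in the block sums
      std::fill(net.bsum.begin(), net.bsum.end(), 0.0);
      for (size_t k = 0; k < net.a.size(); ++k) {
        net.a[k] = 0.0;
        net.set_a(static_cast<int>(k), net.prop(static_cast<int>(k)));
      }
    }
  }

  // return live species only
  List out_toks;
  NumericVector out_n;
  std::vector<int> keep;
  for (size_t s = 0; s < net.sp.size(); ++s)
    if (net.n[s] > 0.0) keep.push_back(static_cast<int>(s));
  List lt(keep.size());
  NumericVector ln(keep.size());
  for (size_t q = 0; q < keep.size(); ++q) {
    lt[q] = IntegerVector(net.sp[keep[q]].toks.begin(), net.sp[keep[q]].toks.end());
    ln[q] = net.n[keep[q]];
  }
  return List::create(_["tokens"] = lt, _["counts"] = ln,
                      _["time"] = t, _["steps"] = steps,
                      _["n_channels"] = static_cast<double>(net.ch_i.size()),
                      _["n_species"] = static_cast<double>(net.sp.size()));
}

// [[Rcpp::export]]
List ssa_enumerate_cpp(List tokens, double kA, double kBC, List opts) {
  Network net;
  NumericVector ones(tokens.size(), 1.0);
  seed_network(net, tokens, ones, kA, kBC, 1e-15, opts);
  const int nc = static_cast<int>(net.ch_i.size());
  List r1(nc), r2(nc), p1(nc), p2(nc);
  NumericVector rate(nc);
  IntegerVector rule(nc);
  for (int c = 0; c < nc; ++c) {
    r1[c] = IntegerVector(net.sp[net.ch_i[c]].toks.begin(), net.sp[net.ch_i[c]].toks.end());
    r2[c] = IntegerVector(net.sp[net.ch_j[c]].toks.begin(), net.sp[net.ch_j[c]].toks.end());
    p1[c] = IntegerVector(net.sp[net.ch_p1[c]].toks.begin(), net.sp[net.ch_p1[c]].toks.end());
    if (net.ch_p2[c] >= 0)
      p2[c] = IntegerVector(net.sp[net.ch_p2[c]].toks.begin(), net.sp[net.ch_p2[c]].toks.end());
    else
      p2[c] = R_NilValue;
    rate[c] = net.ch_rate[c];
    rule[c] = net.ch_rule[c];
  }
  return List::create(_["reactant1"] = r1, _["reactant2"] = r2,
                      _["product1"] = p1, _["product2"] = p2,
                      _["rate"] = rate, _["rule"] = rule);
}
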