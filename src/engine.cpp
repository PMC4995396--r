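// Rejection delay-SSA engine with constant, distributed (gamma) and
// state-dependent delay channels.  Counts are kept as doubles (they are
// small integers); all randomness goes through R's RNG so set.seed() on the
// R side makes every run reproducible.
#include <Rcpp.h>
#include <queue>
#include <vector>
#include <cmath>
using namespace Rcpp;

static const double DELAY_EPS = 1e-9;

// ---------------------------------------------------------------------------
// Lambert W, principal branch, for arguments in [-1/e, 0).  Halley iteration;
// the near -1/e series seeds convergence close to the branch point.
static double lambertW0(double x) {
  const double minx = -0.3678794411714423216;
  if (x < minx) {
    if (x > minx - 1e-12) x = minx;  // clamp tiny numerical undershoot
    else return NA_REAL;
  }
  double w;
  if (x < -0.25) {
    double p = std::sqrt(2.0 * (M_E * x + 1.0));
    w = -1.0 + p - p * p / 3.0;
  } else {
    w = x * std::exp(-x);  // decent seed for small |x|
  }
  for (int i = 0; i < 50; ++i) {
    double ew = std::exp(w);
    double f = w * ew - x;
    if (f == 0.0) break;
    double denom = ew * (w + 1.0) - (w + 2.0) * f / (2.0 * w + 2.0);
    double dw = f / denom;
    if (!std::isfinite(dw)) break;
    w -= dw;
    if (std::fabs(dw) < 1e-13 * (1.0 + std::fabs(w))) break;
  }
  return w;
}

// Closed-form state-dependent delay tau2 solving z^n e^{-z/2} = C, z = k*tau2,
// with C = (1 + C2*y) n! / C1, C1 = x1 - y/(n-1), and the calibrated
// C2 = alpha*(1 - y/beta) - 1/beta.
// Out-of-domain states fall back to the C1=0-branch value or the z = 2n cap
// (the ascending branch's largest reachable root).
static double tau2Closed(double x1, double y, double k, int n) {
  if (x1 < 1.0) stop("state-dependent delay needs x1 >= 1 (got x1 = %f)", x1);
  double logC;
  if (y <= 0.0) {
    logC = std::lgamma(n + 1.0) - std::log(x1);
  } else {
    double C1 = x1 - y / (n - 1.0);
    if (std::fabs(C1) < 1e-12)
      return (n - 1.0) * (1.0 + 1.0 / y) / k;
    double alpha = 3.25 + 7.5 / x1;
    double beta = 11.8 + 8.2 * x1;
    double C2 = alpha * (1.0 - y / beta) - 1.0 / beta;
    double num = 1.0 + C2 * y;
    if (num / C1 <= 0.0)  // thin band between the zeros of C1 and 1+C2*y
      return (n - 1.0) * (1.0 + 1.0 / y) / k;
    logC = std::log(std::fabs(num)) + std::lgamma(n + 1.0) -
           std::log(std::fabs(C1));
  }
  double arg = -std::exp(logC / n) / (2.0 * n);
  if (arg < -std::exp(-1.0)) return 2.0 * n / k;  // beyond the branch point
  double w = lambertW0(arg);
  return -2.0 * n * w / k;
}

// [[Rcpp::export(name = ".cppTau2Closed")]]
NumericVector cppTau2Closed(NumericVector x1, NumericVector y,
                            NumericVector k, IntegerVector n) {
  int m = x1.size();
  NumericVector out(m);
  for (int i = 0; i < m; ++i)
    out[i] = tau2Closed(x1[i], y[i], k[i], n[i]);
  return out;
}

// ---------------------------------------------------------------------------
struct ChannelC {
  int ptype;        // 0 zero-order, 1 first-order mass action, 2 Michaelis-Menten
  double rate;      // k or V
  double K;         // MM constant
  int pspecies;     // reactant species (0-based), -1 for zero-order
  int profile;      // time-varying rate factor index, -1 if none
  std::vector<double> nu;  // consuming stoichiometry (applied at firing)
  std::vector<double> u;   // manifesting stoichiometry (applied at completion)
  int dtype;        // 0 none, 1 constant, 2 gamma, 3 sd linear, 4 sd Michaelis-Menten
  std::vector<double> dpar;
  bool stochTau2;   // sample tau2 from an Erlang with the deterministic mean
  double stochShape;
  bool delayed;
};

struct Event { double time; int channel; int kind; };  // kind 0 fire, 1 complete

typedef std::pair<double, int> QEntry;
typedef std::priority_queue<QEntry, std::vector<QEntry>,
                            std::greater<QEntry> > DelayQueue;

static double propensity(const ChannelC& ch, const std::vector<double>& x,
                         const std::vector<double>& profVal) {
  double a;
  switch (ch.ptype) {
  case 0: a = ch.rate; break;
  case 1: a = ch.rate * x[ch.pspecies]; break;
  default: a = ch.rate * x[ch.pspecies] / (ch.K + x[ch.pspecies]);
  }
  if (ch.profile >= 0) a *= profVal[ch.profile];
  return a;
}

// delay (tau = tau2 - tau1, floored) for a delayed channel, evaluated on the
// state BEFORE the consuming update so x1 still counts the firing molecule.
static double channelDelay(const ChannelC& ch, const std::vector<double>& x,
                           double mu) {
  double tau;
  switch (ch.dtype) {
  case 1:
    return ch.dpar[0];
  case 2:
    return R::rgamma(ch.dpar[0], 1.0 / ch.dpar[1]);
  case 3: {
    int n = (int) ch.dpar[1];
    double x1 = x[(int) ch.dpar[2]];
    double y = x[(int) ch.dpar[3]];
    double tau2 = tau2Closed(x1, y, ch.dpar[0], n);
    if (ch.stochTau2) {
      double shape = ch.stochShape > 0 ? ch.stochShape : n - 1.0;
      tau2 = R::rgamma(shape, tau2 / shape);
    }
    tau = tau2 - mu;
    break;
  }
  default: {  // 4: effective rate from lumped Michaelis-Menten parameters
    int n = (int) ch.dpar[2];
    double x1 = x[(int) ch.dpar[3]];
    double y = x[(int) ch.dpar[4]];
    double keff = ch.dpar[0] / (ch.dpar[1] + y / (n - 1.0));
    double tau2 = tau2Closed(x1, y, keff, n);
    if (ch.stochTau2) {
      double shape = ch.stochShape > 0 ? ch.stochShape : n - 1.0;
      tau2 = R::rgamma(shape, tau2 / shape);
    }
    tau = tau2 - mu;
    break;
  }
  }
  return tau > DELAY_EPS ? tau : DELAY_EPS;
}

static void applyStoich(std::vector<double>& x, const std::vector<double>& s,
                        int channel, const char* what) {
  for (size_t i = 0; i < x.size(); ++i) {
    x[i] += s[i];
    if (x[i] < -1e-9)
      stop("species %d driven negative by %s update of channel %d",
           (int) i + 1, what, channel + 1);
  }
}

// ---------------------------------------------------------------------------
// One SD-SSA realization.  Returns number of events; fills grid records and,
// optionally, the event log.
static int runOne(const std::vector<ChannelC>& channels,
                  const std::vector<double>& x0,
                  const List& profiles,
                  const IntegerVector& initCh, const NumericVector& initCount,
                  const NumericVector& initMT,
                  double tEnd, const NumericVector& recTimes,
                  bool recordEvents, double maxEvents,
                  std::vector<double>& xOut,
                  NumericMatrix* grid,       // S x G, may be NULL
                  std::vector<Event>* events,
                  const IntegerVector& totalSpecies,
                  std::vector<double>* totAtGrid,
                  int& queueLeft) {
  int S = x0.size(), M = channels.size(), G = recTimes.size();
  std::vector<double> x = x0;
  DelayQueue L;
  // pre-scheduled completions of initially present imaginary molecules
  for (int e = 0; e < initCh.size(); ++e)
    for (int c = 0; c < (int) initCount[e]; ++c)
      L.push(QEntry(unif_rand() * initMT[e], initCh[e]));

  // step profiles: value holds from times[i] until times[i+1]
  int P = profiles.size();
  std::vector<NumericVector> pTimes(P), pVals(P);
  std::vector<int> pIdx(P, 0);
  std::vector<double> pCur(P);
  for (int p = 0; p < P; ++p) {
    List pr = profiles[p];
    pTimes[p] = as<NumericVector>(pr["times"]);
    pVals[p] = as<NumericVector>(pr["values"]);
    pCur[p] = pVals[p][0];
  }

  double t = 0.0;
  int gi = 0, nev = 0;
  std::vector<double> a(M);
  while (true) {
    // next profile breakpoint (rates are stepwise-constant between them)
    double tb = R_PosInf;
    for (int p = 0; p < P; ++p)
      if (pIdx[p] + 1 < pTimes[p].size()) {
        double nb = pTimes[p][pIdx[p] + 1];
        if (nb < tb) tb = nb;
      }
    double a0 = 0.0;
    for (int j = 0; j < M; ++j) { a[j] = propensity(channels[j], x, pCur); a0 += a[j]; }
    double mu = a0 > 0.0 ? exp_rand() / a0 : R_PosInf;
    double tFire = t + mu;
    double dMin = L.empty() ? R_PosInf : L.top().first;
    double m = std::min(std::min(tFire, dMin), std::min(tb, tEnd));
    if (grid)
      while (gi < G && recTimes[gi] < m) {
        for (int i = 0; i < S; ++i) (*grid)(i, gi) = x[i];
        if (totAtGrid) {
          double tt = 0.0;
          for (int i = 0; i < totalSpecies.size(); ++i) tt += x[totalSpecies[i]];
          (*totAtGrid)[gi] = tt;
        }
        ++gi;
      }
    if (tEnd <= m) { t = tEnd; break; }
    if (tb <= std::min(tFire, dMin)) {  // rates change; redraw from the new rates
      t = tb;
      for (int p = 0; p < P; ++p)
        while (pIdx[p] + 1 < pTimes[p].size() && pTimes[p][pIdx[p] + 1] <= t) {
          ++pIdx[p]; pCur[p] = pVals[p][pIdx[p]];
        }
      continue;
    }
    if (dMin <= tFire) {  // queued completion wins; discard the drawn waiting time
      int ch = L.top().second;
      L.pop();
      t = dMin;
      applyStoich(x, channels[ch].u, ch, "manifesting");
      if (recordEvents && events) { Event e = {t, ch, 1}; events->push_back(e); }
    } else {
      t = tFire;
      double r2 = unif_rand() * a0, cum = 0.0;
      int j = M - 1;
      for (int jj = 0; jj < M; ++jj) { cum += a[jj]; if (r2 <= cum) { j = jj; break; } }
      if (channels[j].delayed) {
        double tau = channelDelay(channels[j], x, mu);  // state before nu
        L.push(QEntry(t + tau, j));
      }
      applyStoich(x, channels[j].nu, j, "consuming");
      if (recordEvents && events) { Event e = {t, j, 0}; events->push_back(e); }
    }
    if (++nev > maxEvents)
      stop("event budget exceeded (%.0f events before t = %f)", maxEvents, t);
  }
  if (grid)
    while (gi < G && recTimes[gi] <= tEnd) {
      for (int i = 0; i < S; ++i) (*grid)(i, gi) = x[i];
      if (totAtGrid) {
        double tt = 0.0;
        for (int i = 0; i < totalSpecies.size(); ++i) tt += x[totalSpecies[i]];
        (*totAtGrid)[gi] = tt;
      }
      ++gi;
    }
  xOut = x;
  queueLeft = (int) L.size();
  return nev;
}

static std::vector<ChannelC> parseChannels(const List& channels, int S) {
  int M = channels.size();
  std::vector<ChannelC> out(M);
  for (int j = 0; j < M; ++j) {
    List cj = channels[j];
    ChannelC& c = out[j];
    c.ptype = as<int>(cj["ptype"]);
    c.rate = as<double>(cj["rate"]);
    c.K = cj.containsElementNamed("K") ? as<double>(cj["K"]) : 0.0;
    c.pspecies = as<int>(cj["pspecies"]);
    c.profile = as<int>(cj["profile"]);
    NumericVector nu = as<NumericVector>(cj["nu"]);
    NumericVector u = as<NumericVector>(cj["u"]);
    if (nu.size() != S || u.size() != S)
      stop("stoichiometry of channel %d has wrong length", j + 1);
    c.nu.assign(nu.begin(), nu.end());
    c.u.assign(u.begin(), u.end());
    c.dtype = as<int>(cj["dtype"]);
    NumericVector dp = as<NumericVector>(cj["dpar"]);
    c.dpar.assign(dp.begin(), dp.end());
    c.stochTau2 = cj.containsElementNamed("stochTau2") ?
      as<bool>(cj["stochTau2"]) : false;
    c.stochShape = cj.containsElementNamed("stochShape") ?
      as<double>(cj["stochShape"]) : 0.0;
    c.delayed = c.dtype != 0;
  }
  return out;
}

// [[Rcpp::export(name = ".cppRunSDSSA")]]
List cppRunSDSSA(NumericVector x0, List channels, List profiles,
                 IntegerVector initCh, NumericVector initCount,
                 NumericVector initMT, double tEnd, NumericVector recTimes,
                 bool recordEvents, double maxEvents) {
  int S = x0.size();
  std::vector<ChannelC> ch = parseChannels(channels, S);
  std::vector<double> xinit(x0.begin(), x0.end()), xout;
  std::vector<Event> events;
  NumericMatrix grid(S, recTimes.size());
  int queueLeft = 0;
  RNGScope scope;
  int nev = runOne(ch, xinit, profiles, initCh, initCount, initMT, tEnd,
                   recTimes, recordEvents, maxEvents, xout,
                   recTimes.size() ? &grid : (NumericMatrix*) NULL,
                   &events, IntegerVector(0), NULL, queueLeft);
  NumericVector evTime(events.size());
  IntegerVector evCh(events.size()), evKind(events.size());
  for (size_t i = 0; i < events.size(); ++i) {
    evTime[i] = events[i].time;
    evCh[i] = events[i].channel + 1;
    evKind[i] = events[i].kind;
  }
  return List::create(_["finalState"] = NumericVector(xout.begin(), xout.end()),
                      _["counts"] = grid, _["nEvents"] = nev,
                      _["queueRemaining"] = queueLeft,
                      _["eventTime"] = evTime, _["eventChannel"] = evCh,
                      _["eventKind"] = evKind);
}

// Ensemble runner: accumulates per-species mean/SE on the record grid plus
// the mean/SE of the total over a designated species subset.
// [[Rcpp::export(name = ".cppRunEnsemble")]]
List cppRunEnsemble(NumericVector x0, List channels, List profiles,
                    IntegerVector initCh, NumericVector initCount,
                    NumericVector initMT, double tEnd, NumericVector recTimes,
                    int reps, IntegerVector totalSpecies, double maxEvents) {
  int S = x0.size(), G = recTimes.size();
  std::vector<ChannelC> ch = parseChannels(channels, S);
  std::vector<double> xinit(x0.begin(), x0.end()), xout;
  NumericMatrix sum(S, G), sumsq(S, G);
  NumericVector totSum(G), totSumsq(G);
  RNGScope scope;
  for (int r = 0; r < reps; ++r) {
    NumericMatrix grid(S, G);
    std::vector<double> tot(G, 0.0);
    int queueLeft = 0;
    runOne(ch, xinit, profiles, initCh, initCount, initMT, tEnd, recTimes,
           false, maxEvents, xout, &grid, NULL, totalSpecies, &tot, queueLeft);
    for (int g = 0; g < G; ++g) {
      for (int i = 0; i < S; ++i) {
        sum(i, g) += grid(i, g);
        sumsq(i, g) += grid(i, g) * grid(i, g);
      }
      totSum[g] += tot[g];
      totSumsq[g] += tot[g] * tot[g];
    }
    if ((r & 255) == 0) checkUserInterrupt();
  }
  NumericMatrix mean(S, G), se(S, G);
  NumericVector totMean(G), totSE(G);
  for (int g = 0; g < G; ++g) {
    for (int i = 0; i < S; ++i) {
      double m = sum(i, g) / reps;
      mean(i, g) = m;
      double v = reps > 1 ? (sumsq(i, g) - reps * m * m) / (reps - 1.0) : 0.0;
      se(i, g) = v > 0 ? std::sqrt(v / reps) : 0.0;
    }
    double m = totSum[g] / reps;
    totMean[g] = m;
    double v = reps > 1 ? (totSumsq[g] - reps * m * m) / (reps - 1.0) : 0.0;
    totSE[g] = v > 0 ? std::sqrt(v / reps) : 0.0;
  }
  return List::create(_["mean"] = mean, _["se"] = se,
                      _["totalMean"] = totMean, _["totalSE"] = totSE,
                      _["reps"] = reps);
}
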