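// Fixed-step network integrator for Hodgkin-Huxley-style compartments with
// event-triggered AMPA/NMDA synapses, ohmic electrical coupling and discrete
// synaptic-strength noise.
//
// Units project-wide: mV, ms, nS, pF, pA.  dv/dt = (sum of currents pA)/C pF
// gives mV/ms directly.
//
// Gating uses the generalised rate form r(V) = (A + B*V) / (C + exp((D+V)/E)),
// which covers both classic HH alpha/beta functions and sigmoid/exponential
// rates.  Gates advance by exponential Euler; the membrane update is also
// exponential Euler with all conductance-based currents (ionic, synaptic,
// electrical coupling) treated implicitly via the instantaneous conductance
// and its weighted reversal, which keeps the scheme stable for the large
// axonal conductances.

#include <Rcpp.h>
#include <cmath>
#include <vector>
using namespace Rcpp;

static inline double rate_fn(double v, const double* p) {
  // p = A, B, C, D, E
  double den = p[2] + std::exp((p[3] + v) / p[4]);
  if (std::fabs(den) < 1e-7) {
    // removable singularity (e.g. classic HH alpha_m at v = -D); nudge v
    v += 1e-3;
    den = p[2] + std::exp((p[3] + v) / p[4]);
  }
  return (p[0] + p[1] * v) / den;
}

struct GateKin {
  double a[5];
  double b[5];
  double scale;   // multiplies both alpha and beta (kinetic speed)
  int    power;   // exponent of the gate in the conductance product
};

struct CellKin {
  GateKin g[4];   // m, h, n, s
};

// [[Rcpp::export]]
List cpp_run_network(NumericMatrix comp,
                     List kinetics,
                     NumericMatrix coupling,
                     NumericMatrix chem,
                     IntegerVector source_comp,
                     NumericMatrix ext_events,
                     NumericMatrix inj,
                     IntegerVector detect_comp,
                     IntegerVector record_comp,
                     double dt, double duration, int out_every,
                     NumericVector value_set,
                     double mg_vhalf, double mg_slope,
                     double spike_thresh, double min_isi,
                     bool record_gsyn) {
  if (!(dt > 0.0) || !R_finite(dt)) stop("dt must be a positive finite number");
  if (!(duration > 0.0)) stop("duration must be positive");

  const int nc = comp.nrow();
  const int nsteps = (int)std::ceil(duration / dt);

  // --- unpack compartments -------------------------------------------------
  std::vector<double> cm(nc), gna(nc), gkf(nc), gks(nc), gl(nc),
      ena(nc), ek(nc), el(nc), v(nc);
  std::vector<int> kin_idx(nc);
  for (int i = 0; i < nc; ++i) {
    cm[i]  = comp(i, 0); gna[i] = comp(i, 1); gkf[i] = comp(i, 2);
    gks[i] = comp(i, 3); gl[i]  = comp(i, 4); ena[i] = comp(i, 5);
    ek[i]  = comp(i, 6); el[i]  = comp(i, 7);
    kin_idx[i] = (int)comp(i, 8) - 1;
    v[i] = comp(i, 9);
    if (!R_finite(v[i])) stop("non-finite initial voltage in compartment %d", i + 1);
  }

  // --- unpack kinetics -----------------------------------------------------
  const int nk = kinetics.size();
  std::vector<CellKin> kin(nk);
  for (int k = 0; k < nk; ++k) {
    List kk = kinetics[k];
    NumericMatrix r = kk["rates"];          // 8 x 5: am, bm, ah, bh, an, bn, as, bs
    IntegerVector pw = kk["powers"];        // length 4
    NumericVector sc = kk["rate_scale"];    // length 4
    for (int g = 0; g < 4; ++g) {
      for (int j = 0; j < 5; ++j) {
        kin[k].g[g].a[j] = r(2 * g, j);
        kin[k].g[g].b[j] = r(2 * g + 1, j);
      }
      kin[k].g[g].power = pw[g];
      kin[k].g[g].scale = sc[g];
    }
  }

  // gating state initialised at steady state for v0
  std::vector<double> gate(nc * 4);
  for (int i = 0; i < nc; ++i) {
    const CellKin& K = kin[kin_idx[i]];
    for (int g = 0; g < 4; ++g) {
      double al = rate_fn(v[i], K.g[g].a), be = rate_fn(v[i], K.g[g].b);
      double s = al + be;
      gate[i * 4 + g] = (s > 0) ? al / s : 0.0;
    }
  }

  // --- synapses ------------------------------------------------------------
  const int ne = chem.nrow();
  std::vector<int> e_src(ne), e_post(ne), e_perspike(ne);
  std::vector<double> e_ga(ne), e_gn(ne), e_erev(ne), e_scale(ne);
  std::vector<double> dec_ra(ne), dec_da(ne), dec_rn(ne), dec_dn(ne),
      norm_a(ne), norm_n(ne);
  // dual-exponential state per edge per receptor: g = B - A
  std::vector<double> Aa(ne, 0.0), Ba(ne, 0.0), An(ne, 0.0), Bn(ne, 0.0);
  auto dualexp_norm = [](double tr, double td) {
    double tp = std::log(td / tr) * tr * td / (td - tr);
    return std::exp(-tp / td) - std::exp(-tp / tr);
  };
  for (int e = 0; e < ne; ++e) {
    e_src[e]  = (int)chem(e, 0) - 1;
    e_post[e] = (int)chem(e, 1) - 1;
    e_ga[e] = chem(e, 2); e_gn[e] = chem(e, 3); e_erev[e] = chem(e, 4);
    double tra = chem(e, 5), tda = chem(e, 6), trn = chem(e, 7), tdn = chem(e, 8);
    if (!(tra > 0 && tda > tra && trn > 0 && tdn > trn))
      stop("synaptic time constants must satisfy 0 < rise < decay");
    e_scale[e] = chem(e, 9);
    e_perspike[e] = (int)chem(e, 10);
    dec_ra[e] = std::exp(-dt / tra); dec_da[e] = std::exp(-dt / tda);
    dec_rn[e] = std::exp(-dt / trn); dec_dn[e] = std::exp(-dt / tdn);
    norm_a[e] = dualexp_norm(tra, tda);
    norm_n[e] = dualexp_norm(trn, tdn);
  }

  // outgoing edge lists per source id
  int nsrc = source_comp.size();
  {
    for (int e = 0; e < ne; ++e)
      if (e_src[e] + 1 > nsrc) nsrc = e_src[e] + 1;   // external ids beyond internal
  }
  std::vector<std::vector<int> > out_edges(nsrc);
  for (int e = 0; e < ne; ++e) out_edges[e_src[e]].push_back(e);

  // internal source lookup: compartment -> source id (-1 if none)
  std::vector<int> comp2src(nc, -1);
  for (int s = 0; s < source_comp.size(); ++s) comp2src[source_comp[s] - 1] = s;

  // --- detection / recording ----------------------------------------------
  std::vector<int> is_detect(nc, 0);
  for (int i = 0; i < detect_comp.size(); ++i) is_detect[detect_comp[i] - 1] = 1;
  std::vector<double> last_event(nc, -1e9);

  const int nrec = record_comp.size();
  const int nout = nsteps / out_every + 1;
  NumericMatrix vout(nout, nrec);
  NumericMatrix ga_out(record_gsyn ? nout : 1, record_gsyn ? nrec : 1);
  NumericMatrix gn_out(record_gsyn ? nout : 1, record_gsyn ? nrec : 1);
  NumericVector tout(nout);
  std::vector<int> rec_idx(nrec);
  for (int i = 0; i < nrec; ++i) rec_idx[i] = record_comp[i] - 1;

  std::vector<double> spike_comp_v, spike_t;
  std::vector<double> draw_edge, draw_t, draw_val;

  const int nK = value_set.size();
  RNGScope rng;   // per-spike draws use R's RNG stream

  // external events (sorted by time)
  const int nev = ext_events.nrow();
  int ev_ptr = 0;

  // injected currents
  const int ninj = inj.nrow();

  bool ok = true;
  double abort_t = NA_REAL;

  std::vector<double> gacc(nc), gEacc(nc), iconst(nc), vnew_buf(nc);
  std::vector<double> gsyn_a(nc), gsyn_n(nc);

  // record initial state
  for (int i = 0; i < nrec; ++i) vout(0, i) = v[rec_idx[i]];
  tout[0] = 0.0;
  int out_row = 1;

  auto trigger_edge = [&](int e, double tnow) {
    double sc = e_scale[e];
    if (e_perspike[e] && nK > 0) {
      int k = (int)std::floor(unif_rand() * nK);
      if (k >= nK) k = nK - 1;
      double ps = value_set[k];
      sc *= ps;
      draw_edge.push_back(e + 1); draw_t.push_back(tnow); draw_val.push_back(ps);
    }
    if (sc <= 0.0) return;
    double qa = sc * e_ga[e] / norm_a[e];
    double qn = sc * e_gn[e] / norm_n[e];
    Aa[e] += qa; Ba[e] += qa;
    An[e] += qn; Bn[e] += qn;
  };

  for (int step = 0; step < nsteps; ++step) {
    double t = step * dt;
    double tnext = t + dt;

    // deliver external events due in (t, t + dt]
    while (ev_ptr < nev && ext_events(ev_ptr, 1) <= tnext) {
      int s = (int)ext_events(ev_ptr, 0) - 1;
      if (s >= 0 && s < nsrc)
        for (size_t j = 0; j < out_edges[s].size(); ++j)
          trigger_edge(out_edges[s][j], ext_events(ev_ptr, 1));
      ++ev_ptr;
    }

    std::fill(gacc.begin(), gacc.end(), 0.0);
    std::fill(gEacc.begin(), gEacc.end(), 0.0);
    std::fill(iconst.begin(), iconst.end(), 0.0);
    if (record_gsyn) {
      std::fill(gsyn_a.begin(), gsyn_a.end(), 0.0);
      std::fill(gsyn_n.begin(), gsyn_n.end(), 0.0);
    }

    // synaptic decay + instantaneous conductances (Mg block at v(t))
    for (int e = 0; e < ne; ++e) {
      Aa[e] *= dec_ra[e]; Ba[e] *= dec_da[e];
      An[e] *= dec_rn[e]; Bn[e] *= dec_dn[e];
      double ga = Ba[e] - Aa[e];
      double gn = Bn[e] - An[e];
      if (ga <= 0 && gn <= 0) continue;
      int p = e_post[e];
      double blk = 1.0 / (1.0 + std::exp(-(v[p] - mg_vhalf) / mg_slope));
      double ge = ga + gn * blk;
      gacc[p] += ge;
      gEacc[p] += ge * e_erev[e];
      if (record_gsyn) { gsyn_a[p] += ga; gsyn_n[p] += gn; }
    }

    // electrical coupling: conductance toward the partner's current voltage
    for (int c = 0; c < coupling.nrow(); ++c) {
      int a = (int)coupling(c, 0) - 1, b = (int)coupling(c, 1) - 1;
      double gc = coupling(c, 2);
      gacc[a] += gc; gEacc[a] += gc * v[b];
      gacc[b] += gc; gEacc[b] += gc * v[a];
    }

    // injected step currents
    for (int j = 0; j < ninj; ++j) {
      if (t >= inj(j, 2) && t < inj(j, 3))
        iconst[(int)inj(j, 0) - 1] += inj(j, 1);
    }

    // membrane update (exponential Euler on the full conductance balance)
    for (int i = 0; i < nc; ++i) {
      const CellKin& K = kin[kin_idx[i]];
      double vi = v[i];
      double gv[4];
      for (int g = 0; g < 4; ++g) {
        double al = rate_fn(vi, K.g[g].a) * K.g[g].scale;
        double be = rate_fn(vi, K.g[g].b) * K.g[g].scale;
        double s = al + be;
        double x = gate[i * 4 + g];
        if (s > 0) {
          double xinf = al / s;
          x = xinf + (x - xinf) * std::exp(-dt * s);
        }
        if (x < 0) x = 0; else if (x > 1) x = 1;
        gate[i * 4 + g] = x;
        gv[g] = x;
      }
      double pm = 1.0, pn = 1.0, ps = 1.0, ph = 1.0;
      for (int q = 0; q < K.g[0].power; ++q) pm *= gv[0];
      for (int q = 0; q < K.g[1].power; ++q) ph *= gv[1];
      for (int q = 0; q < K.g[2].power; ++q) pn *= gv[2];
      for (int q = 0; q < K.g[3].power; ++q) ps *= gv[3];
      double gm = gna[i] * pm * ph, gkf_i = gkf[i] * pn,
             gks_i = gks[i] * ps;
      double gtot = gm + gkf_i + gks_i + gl[i] + gacc[i];
      double gE = gm * ena[i] + (gkf_i + gks_i) * ek[i] + gl[i] * el[i]
                + gEacc[i] + iconst[i];
      double vnew;
      if (gtot > 1e-12) {
        double vinf = gE / gtot;
        vnew = vinf + (vi - vinf) * std::exp(-dt * gtot / cm[i]);
      } else {
        vnew = vi + dt * gE / cm[i];
      }
      vnew_buf[i] = vnew;
    }

    // crossing detection + event triggering, then commit voltages
    for (int i = 0; i < nc; ++i) {
      double vnew = vnew_buf[i];
      if (is_detect[i] && v[i] < spike_thresh && vnew >= spike_thresh &&
          (tnext - last_event[i]) >= min_isi) {
        double tc = t + dt * (spike_thresh - v[i]) / (vnew - v[i]);
        last_event[i] = tnext;
        spike_comp_v.push_back(i + 1);
        spike_t.push_back(tc);
        int s = comp2src[i];
        if (s >= 0)
          for (size_t j = 0; j < out_edges[s].size(); ++j)
            trigger_edge(out_edges[s][j], tc);
      }
      v[i] = vnew;
      if (std::fabs(vnew) > 200.0) { ok = false; abort_t = tnext; }
    }
    if (!ok) break;

    if ((step + 1) % out_every == 0 && out_row < nout) {
      for (int i = 0; i < nrec; ++i) {
        vout(out_row, i) = v[rec_idx[i]];
        if (record_gsyn) {
          ga_out(out_row, i) = gsyn_a[rec_idx[i]];
          gn_out(out_row, i) = gsyn_n[rec_idx[i]];
        }
      }
      tout[out_row] = tnext;
      ++out_row;
    }
  }

  NumericMatrix spikes(spike_t.size(), 2);
  for (size_t i = 0; i < spike_t.size(); ++i) {
    spikes(i, 0) = spike_comp_v[i];
    spikes(i, 1) = spike_t[i];
  }
  NumericMatrix draws(draw_t.size(), 3);
  for (size_t i = 0; i < draw_t.size(); ++i) {
    draws(i, 0) = draw_edge[i]; draws(i, 1) = draw_t[i]; draws(i, 2) = draw_val[i];
  }
  NumericVector vfinal(nc);
  for (int i = 0; i < nc; ++i) vfinal[i] = v[i];

  List res = List::create(
      _["ok"] = ok, _["abort_time"] = abort_t,
      _["spikes"] = spikes, _["times"] = tout, _["v"] = vout,
      _["per_spike_draws"] = draws, _["v_final"] = vfinal,
      _["n_out"] = out_row);
  if (record_gsyn) { res["g_ampa"] = ga_out; res["g_nmda"] = gn_out; }
  return res;
}
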