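// Core fixed-step simulator: planar 7-segment walker, Hill-type MTUs,
// delay-buffered reflex control, compliant (belt-capable) ground contact,
// and the five disturbance protocols. All state is double precision and
// seed-free: identical configs give bit-identical trajectories.
#include <RcppArmadillo.h>
#include <cmath>
#include <cstring>
#include <vector>
#include <string>
#include <map>
#include <algorithm>

using namespace Rcpp;

static const int NB = 7;            // trunk, thighL, shankL, footL, thighR, shankR, footR
static const int NQ = 9;            // x, y, phi_trunk, hipL, kneeL, ankL, hipR, kneeR, ankR
static const int NMUS = 9;          // per leg
static const int NM = 18;           // both legs
static const char* MUSCLE_NAMES[NMUS] =
  {"HFL","GLU","HAM","RF","VAS","BFSH","GAS","SOL","TA"};
enum { M_HFL, M_GLU, M_HAM, M_RF, M_VAS, M_BFSH, M_GAS, M_SOL, M_TA };

// force-velocity constants (shortening positive, f_v(0)=1, f_v(v_max)=0)
static const double FV_K = 5.0, FV_N = 1.5, FV_ECC = 7.56 * 5.0;
static const double FL_W = 0.56;    // force-length width
static const double SE_EPSREF = 0.04;

struct Vec2 { double x, y; };
static inline Vec2 v2(double x, double y) { Vec2 v; v.x = x; v.y = y; return v; }
static inline Vec2 add(Vec2 a, Vec2 b) { return v2(a.x + b.x, a.y + b.y); }
static inline Vec2 sub(Vec2 a, Vec2 b) { return v2(a.x - b.x, a.y - b.y); }
static inline Vec2 scl(Vec2 a, double s) { return v2(a.x * s, a.y * s); }
static inline Vec2 crossz(double w, Vec2 r) { return v2(-w * r.y, w * r.x); }
static inline double cross2(Vec2 a, Vec2 b) { return a.x * b.y - a.y * b.x; }
static inline Vec2 rot(double c, double s, Vec2 r) { return v2(c * r.x - s * r.y, s * r.x + c * r.y); }

// ---------------------------------------------------------------- bodies ---
struct BodyDef {
  int parent;        // -1 for trunk
  int jcoord;        // generalized coordinate index of the joint (-1 for base)
  double sgn;        // phi = phi_parent + sgn*q + coff
  double coff;
  Vec2 dloc;         // joint position in parent frame
  double m, I, len;
  Vec2 comloc;
};

struct MuscleDef {
  double Fmax, lopt, vmax, lslack;   // vmax in lopt/s
  int delay_steps;
  // geometry per spanned joint (hip, knee, ankle): mode 0 none, 1 constant, 2 cosine
  int mode[3];
  double r[3], thmax[3], thref[3];   // r signed: dl/dtheta = r (mode1) or r*cos(th-thmax) (mode2)
};

// force-length / passive curves ------------------------------------------------
static inline double f_l(double lce, double lopt) {
  double x = std::fabs((lce - lopt) / (lopt * FL_W));
  return std::exp(std::log(0.05) * x * x * x);
}
static inline double f_pe(double lce, double lopt) {
  if (lce <= lopt) return 0.0;
  double x = (lce - lopt) / (lopt * FL_W);
  return x * x;
}
static inline double f_be(double lce, double lopt) {
  double lmin = (1.0 - FL_W) * lopt;
  if (lce >= lmin) return 0.0;
  double x = (lmin - lce) / (lopt * FL_W * 0.5);
  return x * x;
}
static inline double f_v(double vrel) { // vrel = v_ce / v_max, shortening positive
  if (vrel >= 1.0) return 0.0;
  if (vrel >= 0.0) return (1.0 - vrel) / (1.0 + FV_K * vrel);
  double u = -vrel;
  return FV_N - (FV_N - 1.0) / (1.0 + FV_ECC * u);
}
static inline double f_v_inv(double phi) { // returns vrel given force ratio phi
  if (phi < 0.0) phi = 0.0;
  if (phi < 1.0) return (1.0 - phi) / (1.0 + FV_K * phi);
  if (phi >= FV_N) return -1.0;
  double u = ((FV_N - 1.0) / (FV_N - phi) - 1.0) / FV_ECC;
  return std::max(-1.0, -u);
}

// -------------------------------------------------------------- config -----
struct GroundCfg {
  double kn, vref;          // normal: F = kn*pen*(1 + pendot/vref)
  double kt, ct, mu_s, mu_k;
  double belt[2];           // surface velocity per side (m/s, +x)
};

struct DisturbCfg {
  int protocol;             // 0 none, 1 MMR, 2 TR, 3 SR, 4 TRIP, 5 SLIP
  int leg;                  // 0 L, 1 R
  double t0;
  // MMR
  double mmr_amp, mmr_dur; int mmr_bilateral;
  // TR
  int tr_mus[2]; int tr_nmus; double tr_ekin, tr_capfrac, tr_rise, tr_hold, tr_fall;
  // SR
  double sr_amp, sr_vel, sr_holdT, sr_releaseT, sr_kp, sr_kd, sr_taumax;
  // TRIP
  double blk_m, blk_w, blk_h, blk_x, blk_mu, blk_k, blk_cv;
  // SLIP
  double slip_dv, slip_after, slip_accT, slip_sign; int slip_use_snapshot_hs;
};

struct ControlPar {
  double stim_min, tau_act, tau_fade;
  double G_SOL, G_TA, loff_TA, G_SOLTA, G_GAS;
  double G_VAS, q_ko, k_ko, k_dsVAS;
  double th_ref, k_p, k_d, c_GLU_bal, c_HFL_bal, c_HAM_bal;
  double ds_HFL, ds_GLU, sw_BFSH, frac_BFSH;
  double G_HFL, loff_HFL, G_HAMHFL, loff_HAM, G_HAM, G_GLU_sw, k_lean_HFL;
  double s0[NMUS];   // per-muscle baseline (pre-)stimulation
};

static double getpar(const std::map<std::string,double>& m, const char* k, double def) {
  std::map<std::string,double>::const_iterator it = m.find(k);
  return it == m.end() ? def : it->second;
}

// ------------------------------------------------------------- simulator ---
struct Sim {
  // definitions
  BodyDef body[NB];
  MuscleDef mus[NMUS];
  GroundCfg gnd;
  ControlPar cp;
  DisturbCfg dist;
  double dt, g, hip0, fall_frac;
  int pin_xy;               // pin base translation (tests)
  int contact_on, muscles_on, control_mode; // control_mode 0 reflex, 1 external
  double stim_ext[NM];
  double jlim_lo[3], jlim_hi[3], jlim_k, jlim_d; // per joint type hip/knee/ankle
  int trunk_delay_steps, load_delay_steps, knee_delay_steps;

  // state
  double q[NQ], qd[NQ];
  double a[NM], lce[NM], stim[NM], vce_ms[NM], Fse[NM], lmtu_cur[NM];
  double anchor[4]; int anchor_on[4];     // LH, LB, RH, RB
  double grf[4];                          // Lx, Ly, Rx, Ry
  double loadN[2];
  int loaded[2];
  double last_hs[2], prev_hs[2], last_to[2], stride_T;
  double wst[2];
  double belt_now[2];
  long step; double t0_time;
  double Emet, x_start;
  int blown;
  // block (TRIP)
  int blk_active; double blk_xs, blk_ys, blk_vx, blk_vy; int blk_hit; double blk_hit_t;
  // SR
  int sr_on; double sr_qcap; int sr_started;
  // SLIP
  int slip_armed; double slip_t_onset, slip_hs_time; int slip_done;
  double slip_min_hs; int slip_started;
  // TR
  int tr_started; double tr_dl[2]; int tr_capped;

  // delay buffers: 54 muscle signals + lean, leanrate, loadL, loadR, kneeL, kneedL, kneeR, kneedR
  enum { NSIG = 62 };
  int nbuf;
  std::vector<double> buf;  // NSIG x nbuf ring
  long buf_count;           // samples written

  inline double& bufat(int sig, long idx) { return buf[(size_t)sig * nbuf + (idx % nbuf)]; }
  inline double read_delayed(int sig, int dsteps) {
    long idx = buf_count - 1 - dsteps;
    if (idx < 0) idx = 0;
    if (buf_count == 0) return 0.0;
    return buf[(size_t)sig * nbuf + (idx % nbuf)];
  }

  double time() const { return t0_time + step * dt; }

  // ---------------- kinematics scratch
  double phi[NB], cph[NB], sph[NB];
  Vec2 P[NB], VO[NB], AO[NB]; double OM[NB], AL[NB];
  Vec2 fext[NB]; double mext[NB]; // external point-force resultant + moment about body origin

  void fk_pass(const double* qq, const double* qqd, const double* qqdd, int with_vel) {
    for (int i = 0; i < NB; i++) {
      const BodyDef& b = body[i];
      if (b.parent < 0) {
        P[i] = v2(qq[0], qq[1]); phi[i] = qq[2];
        OM[i] = with_vel ? qqd[2] : 0.0; AL[i] = qqdd ? qqdd[2] : 0.0;
        VO[i] = with_vel ? v2(qqd[0], qqd[1]) : v2(0, 0);
        AO[i] = qqdd ? v2(qqdd[0], qqdd[1]) : v2(0, 0);
      } else {
        int p = b.parent;
        Vec2 r = rot(cph[p], sph[p], b.dloc);
        phi[i] = phi[p] + b.sgn * qq[b.jcoord] + b.coff;
        P[i] = add(P[p], r);
        OM[i] = OM[p] + (with_vel ? b.sgn * qqd[b.jcoord] : 0.0);
        AL[i] = AL[p] + (qqdd ? b.sgn * qqdd[b.jcoord] : 0.0);
        VO[i] = add(VO[p], crossz(OM[p], r));
        AO[i] = add(add(AO[p], crossz(AL[p], r)), scl(r, -OM[p] * OM[p]));
      }
      cph[i] = std::cos(phi[i]); sph[i] = std::sin(phi[i]);
    }
  }

  // RNEA: generalized force needed for (q,qd,qdd) under gravity gz and fext
  void rnea(const double* qq, const double* qqd, const double* qqdd,
            double grav, int use_ext, double* tau) {
    fk_pass(qq, qqd, qqdd, 1);
    Vec2 F[NB]; double N[NB];
    for (int i = NB - 1; i >= 0; i--) {
      const BodyDef& b = body[i];
      Vec2 c = rot(cph[i], sph[i], b.comloc);
      Vec2 ac = add(add(AO[i], crossz(AL[i], c)), scl(c, -OM[i] * OM[i]));
      Vec2 fin = v2(b.m * ac.x, b.m * (ac.y + grav)); // inertial minus gravity, at com
      double ni = b.I * AL[i] + cross2(c, fin);
      Vec2 fi = fin;
      if (use_ext) { fi = sub(fi, fext[i]); ni -= mext[i]; }
      // accumulate children (children always have larger index)
      F[i] = fi; N[i] = ni;
      for (int ch = i + 1; ch < NB; ch++) {
        if (body[ch].parent == i) {
          Vec2 rj = sub(P[ch], P[i]);
          F[i] = add(F[i], F[ch]);
          N[i] += N[ch] + cross2(rj, F[ch]);
        }
      }
      if (b.parent < 0) { tau[0] = F[i].x; tau[1] = F[i].y; tau[2] = N[i]; }
      else tau[b.jcoord] = b.sgn * N[i];
    }
  }

  // muscle geometry: anatomical joint angles of a leg (hip, knee, ankle)
  void leg_angles(int leg, double* th, double* thd) {
    int o = 3 + 3 * leg;
    for (int j = 0; j < 3; j++) { th[j] = q[o + j]; thd[j] = qd[o + j]; }
  }
  static double mtu_len(const MuscleDef& md, const double* th) {
    double l = md.lslack + md.lopt;
    for (int j = 0; j < 3; j++) {
      if (md.mode[j] == 1) l += md.r[j] * (th[j] - md.thref[j]);
      else if (md.mode[j] == 2)
        l += md.r[j] * (std::sin(th[j] - md.thmax[j]) - std::sin(md.thref[j] - md.thmax[j]));
    }
    return l;
  }
  static double mtu_arm(const MuscleDef& md, int j, double thj) {
    if (md.mode[j] == 1) return md.r[j];
    if (md.mode[j] == 2) return md.r[j] * std::cos(thj - md.thmax[j]);
    return 0.0;
  }

  // TR imposed length offset at time t (target muscles only)
  double tr_offset(double t, int mi_leg_global) {
    if (dist.protocol != 2 || !tr_started) return 0.0;
    int is_target = 0, k;
    for (k = 0; k < dist.tr_nmus; k++)
      if (dist.tr_mus[k] + NMUS * dist.leg == mi_leg_global) is_target = 1;
    if (!is_target) return 0.0;
    double dl = tr_dl[0];
    for (k = 0; k < dist.tr_nmus; k++)
      if (dist.tr_mus[k] + NMUS * dist.leg == mi_leg_global) dl = tr_dl[k];
    double u = t - dist.t0;
    if (u < 0) return 0.0;
    if (u < dist.tr_rise) return dl * u / dist.tr_rise;
    u -= dist.tr_rise;
    if (u < dist.tr_hold) return dl;
    u -= dist.tr_hold;
    if (u < dist.tr_fall) return dl * (1.0 - u / dist.tr_fall);
    return 0.0;
  }

  // ----------------- one control evaluation (shared with exported wrapper)
  static void control_law(const ControlPar& cp,
                          const double aff[NMUS][3][2],  // [muscle][F,L,V][leg]
                          double lean, double leanrate,
                          const double* load, const double* w_st,
                          const double* ds, const double* swfrac,
                          const double* knee_d, const double* kneed_d,
                          double* out) {
    for (int leg = 0; leg < 2; leg++) {
      double wst_ = w_st[leg], wsw = 1.0 - wst_;
      double bal = cp.k_p * (lean - cp.th_ref) + cp.k_d * leanrate;
      double balp = bal > 0 ? bal : 0, baln = bal < 0 ? -bal : 0;
      double ld = load[leg];
      double s[NMUS];
      double glu_bal = cp.c_GLU_bal * ld * balp;
      s[M_HFL] = wst_ * (cp.c_HFL_bal * ld * baln) + ds[leg] * cp.ds_HFL
        + wsw * (cp.G_HFL * std::max(aff[M_HFL][1][leg] - cp.loff_HFL, 0.0)
                 - cp.G_HAMHFL * std::max(aff[M_HAM][1][leg] - cp.loff_HAM, 0.0)
                 + cp.k_lean_HFL * (lean - cp.th_ref));
      s[M_GLU] = wst_ * glu_bal - ds[leg] * cp.ds_GLU
        + wsw * (cp.G_GLU_sw * aff[M_GLU][0][leg]);
      s[M_HAM] = wst_ * (cp.c_HAM_bal * glu_bal)
        + wsw * (cp.G_HAM * aff[M_HAM][0][leg]);
      s[M_RF]  = 0.0;
      s[M_VAS] = wst_ * (cp.G_VAS * aff[M_VAS][0][leg]
                         - cp.k_ko * std::max(cp.q_ko - knee_d[leg], 0.0) * (kneed_d[leg] < 0 ? 1.0 : 0.0)
                         - cp.k_dsVAS * ds[leg] * load[1 - leg]);
      s[M_BFSH] = wsw * ((swfrac[leg] < cp.frac_BFSH) ? cp.sw_BFSH : 0.0);
      s[M_GAS] = wst_ * (cp.G_GAS * aff[M_GAS][0][leg]);
      s[M_SOL] = wst_ * (cp.G_SOL * aff[M_SOL][0][leg]);   // force afferent only
      s[M_TA]  = cp.G_TA * std::max(aff[M_TA][1][leg] - cp.loff_TA, 0.0)
        - wst_ * (cp.G_SOLTA * aff[M_SOL][0][leg]);
      for (int m = 0; m < NMUS; m++) {
        double v = cp.s0[m] + s[m];
        out[m + NMUS * leg] = v < cp.stim_min ? cp.stim_min : (v > 1.0 ? 1.0 : v);
      }
    }
  }

  // ------------------------------------------------------- main stepping ---
  void compute_stims() {
    if (control_mode == 1) { std::memcpy(stim, stim_ext, sizeof(stim)); return; }
    double aff[NMUS][3][2];
    for (int leg = 0; leg < 2; leg++)
      for (int m = 0; m < NMUS; m++) {
        int base = 3 * (m + NMUS * leg);
        int dsteps = mus[m].delay_steps;
        for (int sgl = 0; sgl < 3; sgl++)
          aff[m][sgl][leg] = read_delayed(base + sgl, dsteps);
      }
    double lean = read_delayed(54, trunk_delay_steps);
    double leanrate = read_delayed(55, trunk_delay_steps);
    double load_d[2] = { read_delayed(56, load_delay_steps), read_delayed(57, load_delay_steps) };
    double knee_d[2] = { read_delayed(58, knee_delay_steps), read_delayed(60, knee_delay_steps) };
    double kneed_d[2] = { read_delayed(59, knee_delay_steps), read_delayed(61, knee_delay_steps) };
    double ds[2], swfrac[2];
    for (int leg = 0; leg < 2; leg++) {
      int contra = 1 - leg;
      ds[leg] = (loaded[leg] && loaded[contra] && last_hs[contra] > last_hs[leg])
        ? wst[leg] * wst[contra] : 0.0;
      double swdur = std::max(0.2, 0.38 * stride_T);
      swfrac[leg] = loaded[leg] ? 0.0 : std::min(1.5, (time() - last_to[leg]) / swdur);
    }
    control_law(cp, aff, lean, leanrate, load_d, wst, ds, swfrac, knee_d, kneed_d, stim);
  }

  void muscle_forces(double* tau) {
    for (int i = 0; i < NB; i++) { fext[i] = v2(0, 0); mext[i] = 0.0; }
    if (!muscles_on) {
      for (int m = 0; m < NM; m++) { Fse[m] = 0; vce_ms[m] = 0; }
      return;
    }
    double th[3], thd[3];
    for (int leg = 0; leg < 2; leg++) {
      leg_angles(leg, th, thd);
      for (int m = 0; m < NMUS; m++) {
        int gi = m + NMUS * leg;
        const MuscleDef& md = mus[m];
        double lm = mtu_len(md, th) + tr_offset(time(), gi);
        lmtu_cur[gi] = lm;
        double lse = lm - lce[gi];
        double eps = (lse - md.lslack) / md.lslack;
        double F = eps > 0 ? md.Fmax * (eps / SE_EPSREF) * (eps / SE_EPSREF) : 0.0;
        Fse[gi] = F;
        double drive = a[gi] * f_l(lce[gi], md.lopt) + f_pe(lce[gi], md.lopt);
        double load_f = F + md.Fmax * f_be(lce[gi], md.lopt);
        double vrel;
        if (drive < 1e-4 && load_f < 1e-6 * md.Fmax) vrel = 0.0;
        else vrel = f_v_inv(load_f / (md.Fmax * std::max(drive, 1e-4)));
        vce_ms[gi] = vrel * md.vmax * md.lopt;
        // joint torques: tau_j = -F * dl/dtheta_j
        for (int j = 0; j < 3; j++)
          if (md.mode[j]) tau[3 + 3 * leg + j] -= F * mtu_arm(md, j, th[j]);
      }
    }
  }

  void joint_limit_torques(double* tau) {
    for (int leg = 0; leg < 2; leg++)
      for (int j = 0; j < 3; j++) {
        int c = 3 + 3 * leg + j;
        double lo = jlim_lo[j], hi = jlim_hi[j];
        if (q[c] < lo) tau[c] += jlim_k * (lo - q[c]) - jlim_d * std::min(qd[c], 0.0);
        else if (q[c] > hi) tau[c] += -jlim_k * (q[c] - hi) - jlim_d * std::max(qd[c], 0.0);
      }
  }

  void contact_pass(const double* heelball, // foot-local points: xh, yh, xb, yb
                    double* grf_out) {
    grf_out[0] = grf_out[1] = grf_out[2] = grf_out[3] = 0;
    if (!contact_on) { loadN[0] = loadN[1] = 0; return; }
    fk_pass(q, qd, NULL, 1);
    for (int leg = 0; leg < 2; leg++) {
      int fb = 3 + 3 * leg; // foot body index
      double fnx = 0, fny = 0;
      for (int pt = 0; pt < 2; pt++) {
        int pi = 2 * leg + pt;
        Vec2 loc = v2(heelball[2 * pt], heelball[2 * pt + 1]);
        Vec2 c = rot(cph[fb], sph[fb], loc);
        Vec2 X = add(P[fb], c);
        Vec2 V = add(VO[fb], crossz(OM[fb], c));
        double pen = -X.y;
        if (pen <= 0) { anchor_on[pi] = 0; continue; }
        double pendot = -V.y;
        double mult = 1.0 + pendot / gnd.vref;
        if (mult < 0) mult = 0; if (mult > 4) mult = 4;   // bound impact damping
        double Fn = gnd.kn * pen * mult;
        if (!anchor_on[pi]) { anchor[pi] = X.x; anchor_on[pi] = 1; }
        anchor[pi] += belt_now[leg] * dt;
        double Ft = -gnd.kt * (X.x - anchor[pi]) - gnd.ct * (V.x - belt_now[leg]);
        double Fmax_f = gnd.mu_s * Fn;
        if (std::fabs(Ft) > Fmax_f) {
          double Fk = gnd.mu_k * Fn * (Ft > 0 ? 1.0 : -1.0);
          Ft = Fk;
          anchor[pi] = X.x + Fk / gnd.kt;
        }
        fext[fb] = add(fext[fb], v2(Ft, Fn));
        mext[fb] += cross2(sub(X, P[fb]), v2(Ft, Fn));
        fnx += Ft; fny += Fn;
      }
      grf_out[2 * leg] = fnx; grf_out[2 * leg + 1] = fny;
      loadN[leg] = fny;
    }
    // TRIP block interactions
    if (blk_active) block_pass();
  }

  void block_pass() {
    // foot points vs block AABB; block vs ground
    double bfx = 0, bfy = 0;
    for (int leg = 0; leg < 2; leg++) {
      int fb = 3 + 3 * leg;
      for (int pt = 0; pt < 2; pt++) {
        Vec2 loc = pt == 0 ? v2(blk_heelball[0], blk_heelball[1]) : v2(blk_heelball[2], blk_heelball[3]);
        Vec2 c = rot(cph[fb], sph[fb], loc);
        Vec2 X = add(P[fb], c);
        Vec2 V = add(VO[fb], crossz(OM[fb], c));
        double pl = X.x - blk_xs, pr = blk_xs + dist.blk_w - X.x;
        double pb = X.y - blk_ys, pt_ = blk_ys + dist.blk_h - X.y;
        if (pl <= 0 || pr <= 0 || pb <= 0 || pt_ <= 0) continue;
        double pmin = std::min(std::min(pl, pr), std::min(pb, pt_));
        Vec2 n; // outward normal (on foot) from block face
        if (pmin == pl) n = v2(-1, 0);
        else if (pmin == pr) n = v2(1, 0);
        else if (pmin == pt_) n = v2(0, 1);
        else n = v2(0, -1);
        double vreln = (V.x - blk_vx) * n.x + (V.y - blk_vy) * n.y;
        double Fn = dist.blk_k * pmin * (1.0 - dist.blk_cv * vreln);
        if (Fn < 0) Fn = 0;
        // tangential (regularized Coulomb)
        Vec2 tdir = v2(-n.y, n.x);
        double vrelt = (V.x - blk_vx) * tdir.x + (V.y - blk_vy) * tdir.y;
        double Ft = -dist.blk_mu * Fn * std::tanh(vrelt / 0.05);
        Vec2 F = add(scl(n, Fn), scl(tdir, Ft));
        fext[fb] = add(fext[fb], F);
        mext[fb] += cross2(sub(X, P[fb]), F);
        bfx -= F.x; bfy -= F.y;
        if (!blk_hit) { blk_hit = 1; blk_hit_t = time(); }
      }
    }
    // block-ground
    double pen = -blk_ys;
    double Fn = 0;
    if (pen > 0) {
      Fn = gnd.kn * pen * (1.0 - blk_vy / gnd.vref);
      if (Fn < 0) Fn = 0;
      bfy += Fn;
      bfx += -0.8 * Fn * std::tanh(blk_vx / 0.02);
    }
    // integrate block (semi-implicit)
    blk_vx += dt * bfx / dist.blk_m;
    blk_vy += dt * (bfy / dist.blk_m - g);
    blk_xs += dt * blk_vx;
    blk_ys += dt * blk_vy;
  }
  double blk_heelball[4];

  void servo_torque(double* tau) {
    if (dist.protocol != 3 || dist.sr_amp == 0.0) return;
    double t = time();
    if (t < dist.t0) return;
    int c = 5 + 3 * dist.leg;
    if (!sr_started) { sr_started = 1; sr_qcap = q[c]; }
    double Tr = dist.sr_amp / dist.sr_vel;
    double u = t - dist.t0, off, offd;
    if (u < Tr) { off = dist.sr_vel * u; offd = dist.sr_vel; }
    else if (u < Tr + dist.sr_holdT) { off = dist.sr_amp; offd = 0; }
    else if (u < Tr + dist.sr_holdT + dist.sr_releaseT) {
      double w = (u - Tr - dist.sr_holdT) / dist.sr_releaseT;
      off = dist.sr_amp * (1.0 - w); offd = -dist.sr_amp / dist.sr_releaseT;
    } else return;
    double tq = dist.sr_kp * (sr_qcap + off - q[c]) + dist.sr_kd * (offd - qd[c]);
    if (tq > dist.sr_taumax) tq = dist.sr_taumax;
    if (tq < -dist.sr_taumax) tq = -dist.sr_taumax;
    tau[c] += tq;
  }

  int pend_cnt[2];          // debounce: steps the opposite contact state persisted
  int debounce_steps;

  void update_events() {
    for (int leg = 0; leg < 2; leg++) {
      // a state flip registers only after it persists for the debounce span;
      // the event is timestamped at the first step of the persistent run
      int want = loaded[leg] ? (loadN[leg] < 15.0) : (loadN[leg] > 30.0);
      if (want) pend_cnt[leg]++; else pend_cnt[leg] = 0;
      if (pend_cnt[leg] >= debounce_steps) {
        double t_ev = time() - (pend_cnt[leg] - 1) * dt;
        pend_cnt[leg] = 0;
        if (!loaded[leg]) {
          loaded[leg] = 1;
          if (last_hs[leg] >= 0) {
            double T = t_ev - last_hs[leg];
            if (T > 0.4 && T < 2.5)
              stride_T = (stride_T > 0) ? 0.5 * stride_T + 0.5 * T : T;
          }
          prev_hs[leg] = last_hs[leg];
          last_hs[leg] = t_ev;
          ev_t.push_back(t_ev); ev_leg.push_back(leg); ev_type.push_back(0);
        } else {
          loaded[leg] = 0;
          last_to[leg] = t_ev;
          ev_t.push_back(t_ev); ev_leg.push_back(leg); ev_type.push_back(1);
        }
      }
      double target = loaded[leg] ? 1.0 : 0.0;
      wst[leg] += dt * (target - wst[leg]) / cp.tau_fade;
    }
    // SLIP trigger
    if (dist.protocol == 5 && dist.slip_dv != 0.0 && !slip_armed && !slip_done) {
      double hs = -1;
      if (dist.slip_use_snapshot_hs && last_hs[dist.leg] >= 0) hs = last_hs[dist.leg];
      else if (!dist.slip_use_snapshot_hs && last_hs[dist.leg] > t0_time) hs = last_hs[dist.leg];
      if (hs > slip_min_hs && hs >= 0) {
        slip_armed = 1; slip_hs_time = hs; slip_t_onset = hs + dist.slip_after;
      }
    }
  }

  void update_belts() {
    belt_now[0] = gnd.belt[0]; belt_now[1] = gnd.belt[1];
    if (dist.protocol == 5 && slip_armed) {
      double t = time();
      if (t >= slip_t_onset) {
        // the surface change must catch the foot in stance: if the leg is
        // airborne at onset (a heel-tap artifact), re-arm on its next strike
        if (!slip_started && !loaded[dist.leg]) {
          slip_min_hs = slip_hs_time; slip_armed = 0;
          return;
        }
        slip_started = 1;
        double w = std::min(1.0, (t - slip_t_onset) / std::max(1e-6, dist.slip_accT));
        belt_now[dist.leg] += dist.slip_sign * dist.slip_dv * w;
        if (w >= 1.0) slip_done = 1;
      }
    }
  }

  void record_afferents() {
    double t = time();
    int mmr_on = (dist.protocol == 1 && dist.mmr_amp != 0.0 &&
                  t >= dist.t0 && t < dist.t0 + dist.mmr_dur);
    for (int leg = 0; leg < 2; leg++)
      for (int m = 0; m < NMUS; m++) {
        int gi = m + NMUS * leg;
        int base = 3 * gi;
        double add_p = 0.0;
        if (mmr_on && (dist.mmr_bilateral || leg == dist.leg)) add_p = dist.mmr_amp;
        bufat(base + 0, buf_count) = Fse[gi] / mus[m].Fmax + add_p;
        bufat(base + 1, buf_count) = lce[gi] / mus[m].lopt + add_p;
        bufat(base + 2, buf_count) = vce_ms[gi] / (mus[m].vmax * mus[m].lopt) + add_p;
      }
    double lean = M_PI / 2.0 - q[2];
    bufat(54, buf_count) = lean;
    bufat(55, buf_count) = -qd[2];
    double mg = 0; for (int i = 0; i < NB; i++) mg += body[i].m;
    mg *= g > 0 ? g : 9.81;
    bufat(56, buf_count) = std::min(1.0, loadN[0] / mg);
    bufat(57, buf_count) = std::min(1.0, loadN[1] / mg);
    bufat(58, buf_count) = q[4];  bufat(59, buf_count) = qd[4];
    bufat(60, buf_count) = q[7];  bufat(61, buf_count) = qd[7];
    buf_count++;
  }

  std::vector<double> ev_t; std::vector<int> ev_leg, ev_type;

  // mass matrix + forward dynamics step
  arma::mat Mm; arma::vec hh, rhs;
  std::vector<int> free_idx;

  void dynamics_step(const double* foot_pts) {
    double tau[NQ]; for (int i = 0; i < NQ; i++) tau[i] = 0;
    update_belts();
    compute_stims();
    muscle_forces(tau);      // fills fext reset + muscle torques
    contact_pass(foot_pts, grf);
    joint_limit_torques(tau);
    servo_torque(tau);
    // bias h = RNEA(q, qd, 0) with gravity + ext forces
    double h[NQ], col[NQ], zero[NQ];
    for (int i = 0; i < NQ; i++) zero[i] = 0;
    rnea(q, qd, NULL, g, 1, h);
    // mass matrix
    Vec2 sf[NB]; double sm[NB];
    for (int i = 0; i < NB; i++) { sf[i] = fext[i]; sm[i] = mext[i]; fext[i] = v2(0,0); mext[i] = 0; }
    double ej[NQ];
    for (int j = 0; j < NQ; j++) {
      for (int i = 0; i < NQ; i++) ej[i] = 0;
      ej[j] = 1;
      rnea(q, zero, ej, 0.0, 0, col);
      for (int i = 0; i < NQ; i++) Mm(i, j) = col[i];
    }
    for (int i = 0; i < NB; i++) { fext[i] = sf[i]; mext[i] = sm[i]; }
    for (int i = 0; i < NQ; i++) rhs(i) = tau[i] - h[i];
    if (!Mm.is_finite() || !rhs.is_finite()) { blown = 1; return; }
    // solve (optionally pinned base translation)
    int nf = (int)free_idx.size();
    arma::vec qdd(NQ, arma::fill::zeros);
    if (nf == NQ) {
      arma::vec sol = arma::solve(Mm, rhs, arma::solve_opts::likely_sympd);
      qdd = sol;
    } else {
      arma::uvec fi(nf);
      for (int i = 0; i < nf; i++) fi(i) = free_idx[i];
      arma::mat Ms = Mm.submat(fi, fi);
      arma::vec rs = rhs.elem(fi);
      arma::vec sol = arma::solve(Ms, rs, arma::solve_opts::likely_sympd);
      for (int i = 0; i < nf; i++) qdd(free_idx[i]) = sol(i);
    }
    // semi-implicit Euler
    for (int i = 0; i < NQ; i++) { qd[i] += dt * qdd(i); }
    if (pin_xy) { qd[0] = 0; qd[1] = 0; }
    for (int i = 0; i < NQ; i++) { q[i] += dt * qd[i]; }
    // muscle state integration + metabolic energy
    double erate = 0.0;
    for (int leg = 0; leg < 2; leg++)
      for (int m = 0; m < NMUS; m++) {
        int gi = m + NMUS * leg;
        const MuscleDef& md = mus[m];
        lce[gi] -= dt * vce_ms[gi];   // shortening positive
        double lo = 0.2 * md.lopt, hi = 1.8 * md.lopt;
        if (lce[gi] < lo) lce[gi] = lo;
        if (lce[gi] > hi) lce[gi] = hi;
        a[gi] += dt * (stim[gi] - a[gi]) / cp.tau_act;
        if (a[gi] < 0) a[gi] = 0; if (a[gi] > 1) a[gi] = 1;
        if (muscles_on) {
          double w = Fse[gi] * vce_ms[gi];
          erate += met_alphaA * a[gi] * a[gi] * md.Fmax * md.lopt
            + met_alphaS * std::max(w, 0.0) + met_alphaL * std::max(-w, 0.0)
            + std::max(w, 0.0);
        }
      }
    Emet += dt * erate;
    // TR start
    if (dist.protocol == 2 && !tr_started && time() >= dist.t0) {
      double Fsum = 0;
      for (int k = 0; k < dist.tr_nmus; k++)
        Fsum += Fse[dist.tr_mus[k] + NMUS * dist.leg];
      double dl = dist.tr_ekin / std::max(Fsum, 1e-6);
      tr_capped = 0;
      for (int k = 0; k < dist.tr_nmus; k++) {
        double cap = dist.tr_capfrac * mus[dist.tr_mus[k]].lopt;
        tr_dl[k] = std::min(dl, cap);
        if (dl > cap) tr_capped = 1;
      }
      tr_started = 1;
    }
    update_events();
    record_afferents();
    step++;
  }
  double met_alphaA, met_alphaS, met_alphaL;

  double kinetic_energy() {
    fk_pass(q, qd, NULL, 1);
    double ke = 0;
    for (int i = 0; i < NB; i++) {
      Vec2 c = rot(cph[i], sph[i], body[i].comloc);
      Vec2 vc = add(VO[i], crossz(OM[i], c));
      ke += 0.5 * body[i].m * (vc.x * vc.x + vc.y * vc.y) + 0.5 * body[i].I * OM[i] * OM[i];
    }
    return ke;
  }
  double potential_energy() {
    fk_pass(q, qd, NULL, 0);
    double pe = 0;
    for (int i = 0; i < NB; i++) {
      Vec2 c = rot(cph[i], sph[i], body[i].comloc);
      pe += body[i].m * g * (P[i].y + c.y);
    }
    return pe;
  }
};

// ------------------------------------------------------------ cfg parsing --
static std::map<std::string,double> named_to_map(SEXP x) {
  std::map<std::string,double> out;
  if (Rf_isNull(x)) return out;
  NumericVector v(x);
  CharacterVector nm = v.names();
  for (int i = 0; i < v.size(); i++) out[as<std::string>(nm[i])] = v[i];
  return out;
}

static void parse_body(Sim& S, List body) {
  double m_hat = body["m_hat"], m_th = body["m_th"], m_sh = body["m_sh"], m_ft = body["m_ft"];
  double l_hat = body["l_hat"], l_th = body["l_th"], l_sh = body["l_sh"];
  double d_hat = body["d_hat"], d_th = body["d_th"], d_sh = body["d_sh"];
  double I_hat = body["I_hat"], I_th = body["I_th"], I_sh = body["I_sh"], I_ft = body["I_ft"];
  double fx_com = body["foot_x_com"], fy_com = body["foot_y_com"];
  S.hip0 = body["hip0"];
  // trunk
  S.body[0].parent = -1; S.body[0].jcoord = -1; S.body[0].sgn = 0; S.body[0].coff = 0;
  S.body[0].dloc = v2(0, 0); S.body[0].m = m_hat; S.body[0].I = I_hat; S.body[0].len = l_hat;
  S.body[0].comloc = v2(d_hat, 0);
  for (int leg = 0; leg < 2; leg++) {
    int b = 1 + 3 * leg, c0 = 3 + 3 * leg;
    S.body[b].parent = 0; S.body[b].jcoord = c0; S.body[b].sgn = 1; S.body[b].coff = -M_PI;
    S.body[b].dloc = v2(0, 0); S.body[b].m = m_th; S.body[b].I = I_th; S.body[b].len = l_th;
    S.body[b].comloc = v2(d_th, 0);
    S.body[b+1].parent = b; S.body[b+1].jcoord = c0 + 1; S.body[b+1].sgn = -1; S.body[b+1].coff = 0;
    S.body[b+1].dloc = v2(l_th, 0); S.body[b+1].m = m_sh; S.body[b+1].I = I_sh; S.body[b+1].len = l_sh;
    S.body[b+1].comloc = v2(d_sh, 0);
    S.body[b+2].parent = b + 1; S.body[b+2].jcoord = c0 + 2; S.body[b+2].sgn = 1; S.body[b+2].coff = M_PI / 2;
    S.body[b+2].dloc = v2(l_sh, 0); S.body[b+2].m = m_ft; S.body[b+2].I = I_ft; S.body[b+2].len = 0;
    S.body[b+2].comloc = v2(fx_com, fy_com);
  }
}

static void parse_muscles(Sim& S, List ml, double dt) {
  NumericMatrix par = ml["par"];        // 9 x (Fmax, lopt, vmax, lslack, delay)
  NumericMatrix geo = ml["geom"];       // 9 x 12 (mode,r,thmax,thref per joint)
  for (int m = 0; m < NMUS; m++) {
    MuscleDef& d = S.mus[m];
    d.Fmax = par(m, 0); d.lopt = par(m, 1); d.vmax = par(m, 2); d.lslack = par(m, 3);
    d.delay_steps = (int)std::lround(par(m, 4) / dt);
    for (int j = 0; j < 3; j++) {
      d.mode[j] = (int)geo(m, 4 * j);
      d.r[j] = geo(m, 4 * j + 1);
      d.thmax[j] = geo(m, 4 * j + 2);
      d.thref[j] = geo(m, 4 * j + 3);
    }
  }
}

static void parse_control(Sim& S, SEXP params) {
  std::map<std::string,double> p = named_to_map(params);
  ControlPar& c = S.cp;
  c.stim_min = getpar(p, "stim_min", 0.01);
  c.tau_act = getpar(p, "tau_act", 0.01);
  c.tau_fade = getpar(p, "tau_fade", 0.01);
  c.G_SOL = getpar(p, "G_SOL", 1.2);
  c.G_TA = getpar(p, "G_TA", 1.1);
  c.loff_TA = getpar(p, "loff_TA", 0.72);
  c.G_SOLTA = getpar(p, "G_SOLTA", 0.6);
  c.G_GAS = getpar(p, "G_GAS", 1.1);
  c.G_VAS = getpar(p, "G_VAS", 1.2);
  c.q_ko = getpar(p, "q_ko", 0.15);
  c.k_ko = getpar(p, "k_ko", 2.0);
  c.k_dsVAS = getpar(p, "k_dsVAS", 0.6);
  c.th_ref = getpar(p, "th_ref", 0.1);
  c.k_p = getpar(p, "k_p", 1.5);
  c.k_d = getpar(p, "k_d", 0.3);
  c.c_GLU_bal = getpar(p, "c_GLU_bal", 0.7);
  c.c_HFL_bal = getpar(p, "c_HFL_bal", 0.7);
  c.c_HAM_bal = getpar(p, "c_HAM_bal", 0.5);
  c.ds_HFL = getpar(p, "ds_HFL", 0.4);
  c.ds_GLU = getpar(p, "ds_GLU", 0.25);
  c.sw_BFSH = getpar(p, "sw_BFSH", 0.2);
  c.frac_BFSH = getpar(p, "frac_BFSH", 0.3);
  c.G_HFL = getpar(p, "G_HFL", 0.35);
  c.loff_HFL = getpar(p, "loff_HFL", 0.65);
  c.G_HAMHFL = getpar(p, "G_HAMHFL", 0.5);
  c.loff_HAM = getpar(p, "loff_HAM", 0.85);
  c.G_HAM = getpar(p, "G_HAM", 0.25);
  c.G_GLU_sw = getpar(p, "G_GLU_sw", 0.25);
  c.k_lean_HFL = getpar(p, "k_lean_HFL", 0.35);
  for (int m = 0; m < NMUS; m++) {
    std::string key = std::string("s0_") + MUSCLE_NAMES[m];
    c.s0[m] = getpar(p, key.c_str(), 0.01);
  }
}

static void parse_disturb(Sim& S, List d) {
  DisturbCfg& D = S.dist;
  std::memset(&D, 0, sizeof(D));
  D.protocol = as<int>(d["protocol"]);
  D.leg = d.containsElementNamed("leg") ? as<int>(d["leg"]) : 0;
  D.t0 = d.containsElementNamed("t0") ? as<double>(d["t0"]) : 0.0;
  if (D.protocol == 1) {
    D.mmr_amp = as<double>(d["amp"]); D.mmr_dur = as<double>(d["dur"]);
    D.mmr_bilateral = as<int>(d["bilateral"]);
  } else if (D.protocol == 2) {
    IntegerVector tm = d["muscles"];
    D.tr_nmus = std::min((int)tm.size(), 2);
    for (int i = 0; i < D.tr_nmus; i++) D.tr_mus[i] = tm[i];
    D.tr_ekin = as<double>(d["ekin"]); D.tr_capfrac = as<double>(d["cap_frac"]);
    D.tr_rise = as<double>(d["rise"]); D.tr_hold = as<double>(d["hold"]);
    D.tr_fall = as<double>(d["fall"]);
  } else if (D.protocol == 3) {
    D.sr_amp = as<double>(d["amp"]); D.sr_vel = as<double>(d["vel"]);
    D.sr_holdT = as<double>(d["hold"]); D.sr_releaseT = as<double>(d["release"]);
    D.sr_kp = as<double>(d["kp"]); D.sr_kd = as<double>(d["kd"]);
    D.sr_taumax = as<double>(d["tau_max"]);
  } else if (D.protocol == 4) {
    D.blk_m = as<double>(d["mass"]); D.blk_w = as<double>(d["width"]);
    D.blk_h = as<double>(d["height"]); D.blk_x = as<double>(d["x_face"]);
    D.blk_mu = as<double>(d["mu"]); D.blk_k = as<double>(d["k"]);
    D.blk_cv = as<double>(d["cv"]);
  } else if (D.protocol == 5) {
    D.slip_dv = as<double>(d["dv"]); D.slip_after = as<double>(d["after_hs"]);
    D.slip_accT = as<double>(d["accel_T"]); D.slip_sign = as<double>(d["sign"]);
    D.slip_use_snapshot_hs = as<int>(d["use_snapshot_hs"]);
  }
}

// -------------------------------------------------------------- [[export]] --

// [[Rcpp::export]]
List rg_sim_cpp(List cfg) {
  Sim S;
  S.dt = as<double>(cfg["dt"]);
  S.g = as<double>(cfg["gravity"]);
  S.pin_xy = as<int>(cfg["pin_base"]);
  S.contact_on = as<int>(cfg["contact_on"]);
  S.muscles_on = as<int>(cfg["muscles_on"]);
  S.fall_frac = as<double>(cfg["fall_frac"]);
  double duration = as<double>(cfg["duration"]);
  int record_stride = as<int>(cfg["record_stride"]);

  parse_body(S, cfg["body"]);
  parse_muscles(S, cfg["muscles"], S.dt);
  parse_control(S, cfg["control"]);
  List gl = cfg["ground"];
  S.gnd.kn = gl["kn"]; S.gnd.vref = gl["vref"]; S.gnd.kt = gl["kt"]; S.gnd.ct = gl["ct"];
  S.gnd.mu_s = gl["mu_s"]; S.gnd.mu_k = gl["mu_k"];
  NumericVector bv = gl["belt"]; S.gnd.belt[0] = bv[0]; S.gnd.belt[1] = bv[1];
  parse_disturb(S, cfg["disturb"]);

  NumericVector jlo = cfg["jlim_lo"], jhi = cfg["jlim_hi"];
  for (int j = 0; j < 3; j++) { S.jlim_lo[j] = jlo[j]; S.jlim_hi[j] = jhi[j]; }
  S.jlim_k = as<double>(cfg["jlim_k"]); S.jlim_d = as<double>(cfg["jlim_d"]);
  NumericVector fpt = cfg["foot_pts"]; // xh, yh, xb, yb in foot frame
  double foot_pts[4] = { fpt[0], fpt[1], fpt[2], fpt[3] };
  for (int i = 0; i < 4; i++) S.blk_heelball[i] = fpt[i];
  S.debounce_steps = std::max(1, (int)std::lround(as<double>(cfg["debounce"]) / S.dt));
  S.pend_cnt[0] = S.pend_cnt[1] = 0;
  S.trunk_delay_steps = (int)std::lround(as<double>(cfg["delay_trunk"]) / S.dt);
  S.load_delay_steps = (int)std::lround(as<double>(cfg["delay_load"]) / S.dt);
  S.knee_delay_steps = (int)std::lround(as<double>(cfg["delay_knee"]) / S.dt);
  NumericVector met = cfg["metabolic"];
  S.met_alphaA = met[0]; S.met_alphaS = met[1]; S.met_alphaL = met[2];

  S.control_mode = as<int>(cfg["control_mode"]);
  if (S.control_mode == 1) {
    NumericVector se = cfg["stim_ext"];
    for (int i = 0; i < NM; i++) S.stim_ext[i] = se[i];
  }

  // buffers
  int maxd = std::max(S.trunk_delay_steps, std::max(S.load_delay_steps, S.knee_delay_steps));
  for (int m = 0; m < NMUS; m++) maxd = std::max(maxd, S.mus[m].delay_steps);
  S.nbuf = maxd + 2;
  S.buf.assign((size_t)Sim::NSIG * S.nbuf, 0.0);
  S.buf_count = 0;

  // init state
  List init = cfg["init"];
  std::string itype = as<std::string>(init["type"]);
  S.step = 0; S.t0_time = 0; S.Emet = 0; S.blown = 0;
  S.stride_T = 1.1;
  for (int i = 0; i < 2; i++) { S.loaded[i] = 0; S.last_hs[i] = -1; S.prev_hs[i] = -1; S.last_to[i] = 0; S.wst[i] = 0; }
  for (int i = 0; i < 4; i++) { S.anchor[i] = 0; S.anchor_on[i] = 0; S.grf[i] = 0; }
  S.loadN[0] = S.loadN[1] = 0;
  for (int i = 0; i < NM; i++) {
    S.a[i] = 0.01; S.stim[i] = 0.01; S.vce_ms[i] = 0; S.Fse[i] = 0;
    S.lce[i] = 0.1; S.lmtu_cur[i] = 0;
  }
  S.blk_active = 0; S.blk_hit = 0; S.blk_hit_t = -1;
  S.sr_on = 0; S.sr_started = 0; S.sr_qcap = 0;
  S.slip_armed = 0; S.slip_done = 0; S.slip_t_onset = -1; S.slip_hs_time = -1;
  S.slip_min_hs = -1; S.slip_started = 0;
  S.tr_started = 0; S.tr_capped = 0; S.tr_dl[0] = S.tr_dl[1] = 0;
  S.belt_now[0] = S.gnd.belt[0]; S.belt_now[1] = S.gnd.belt[1];

  if (itype == "pose") {
    NumericVector q0 = init["q"], qd0 = init["qd"];
    for (int i = 0; i < NQ; i++) { S.q[i] = q0[i]; S.qd[i] = qd0[i]; }
    double apre = init.containsElementNamed("a0") ? as<double>(init["a0"]) : 0.01;
    double th[3], thd[3];
    for (int leg = 0; leg < 2; leg++) {
      S.leg_angles(leg, th, thd);
      for (int m = 0; m < NMUS; m++) {
        int gi = m + NMUS * leg;
        double lm = Sim::mtu_len(S.mus[m], th);
        double l0 = lm - S.mus[m].lslack;
        double lo = 0.35 * S.mus[m].lopt, hi = 1.6 * S.mus[m].lopt;
        S.lce[gi] = std::min(std::max(l0, lo), hi);
        S.a[gi] = apre;
      }
    }
    if (init.containsElementNamed("lce")) {
      NumericVector lc = init["lce"];
      for (int i = 0; i < NM; i++) S.lce[i] = lc[i];
    }
  } else { // snapshot
    List sn = init["snapshot"];
    NumericVector q0 = sn["q"], qd0 = sn["qd"], a0 = sn["a"], lc = sn["lce"];
    for (int i = 0; i < NQ; i++) { S.q[i] = q0[i]; S.qd[i] = qd0[i]; }
    for (int i = 0; i < NM; i++) { S.a[i] = a0[i]; S.lce[i] = lc[i]; }
    S.t0_time = as<double>(sn["t"]);
    NumericVector an = sn["anchor"]; IntegerVector ao = sn["anchor_on"];
    for (int i = 0; i < 4; i++) { S.anchor[i] = an[i]; S.anchor_on[i] = ao[i]; }
    IntegerVector ld = sn["loaded"];
    NumericVector lh = sn["last_hs"], ph = sn["prev_hs"], lt = sn["last_to"], ws = sn["wst"];
    for (int i = 0; i < 2; i++) {
      S.loaded[i] = ld[i]; S.last_hs[i] = lh[i]; S.prev_hs[i] = ph[i];
      S.last_to[i] = lt[i]; S.wst[i] = ws[i];
    }
    S.stride_T = as<double>(sn["stride_T"]);
    NumericMatrix bm = sn["buffers"];
    long bc = (long)as<double>(sn["buf_count"]);
    // restore most recent min(bc, nbuf) samples
    long nrest = std::min<long>(bc, S.nbuf);
    S.buf_count = bc;
    for (long k = bc - nrest; k < bc; k++)
      for (int sg = 0; sg < Sim::NSIG; sg++)
        S.bufat(sg, k) = bm(sg, (int)(k - (bc - nrest)));
  }
  S.x_start = S.q[0];

  // free coordinate mask
  S.free_idx.clear();
  for (int i = 0; i < NQ; i++) {
    if (S.pin_xy && i < 2) continue;
    S.free_idx.push_back(i);
  }
  S.Mm.set_size(NQ, NQ); S.hh.set_size(NQ); S.rhs.set_size(NQ);

  if (S.dist.protocol == 4 && S.dist.blk_m > 0) {   // massless limit: no obstacle
    S.blk_active = 1;
    S.blk_xs = S.dist.blk_x; S.blk_ys = 0.0; S.blk_vx = 0; S.blk_vy = 0;
  }

  // snapshot capture request
  int snap_want = 0, snap_leg = 0; double snap_after = 0; int snap_taken = 0;
  List snap_out = R_NilValue;
  if (cfg.containsElementNamed("snapshot_at") && !Rf_isNull(cfg["snapshot_at"])) {
    List sa = cfg["snapshot_at"];
    snap_want = 1; snap_leg = as<int>(sa["leg"]); snap_after = as<double>(sa["after"]);
  }

  long nsteps = (long)std::lround(duration / S.dt);
  long nrec = nsteps / record_stride + 1;
  int NCOL = 36 + NM * 6;
  NumericMatrix traj(nrec, NCOL);
  long irec = 0;
  int fall = 0; double fall_t = -1;

  // initial pass to populate forces for row 0
  size_t ev_mark = 0;
  for (long st = 0; st <= nsteps; st++) {
    if (st % record_stride == 0 && irec < nrec) {
      traj(irec, 0) = S.time();
      for (int i = 0; i < NQ; i++) { traj(irec, 1 + i) = S.q[i]; traj(irec, 10 + i) = S.qd[i]; }
      for (int i = 0; i < 4; i++) traj(irec, 19 + i) = S.grf[i];
      double mg = 0; for (int i = 0; i < NB; i++) mg += S.body[i].m;
      mg *= (S.g > 0 ? S.g : 9.81);
      traj(irec, 23) = S.loadN[0] / mg; traj(irec, 24) = S.loadN[1] / mg;
      traj(irec, 25) = S.wst[0]; traj(irec, 26) = S.wst[1];
      for (int leg = 0; leg < 2; leg++) {
        double sfrac = (S.last_hs[leg] >= 0 && S.stride_T > 0)
          ? std::max(0.0, S.time() - S.last_hs[leg]) / S.stride_T : 0.0;
        sfrac -= std::floor(sfrac);
        traj(irec, 27 + leg) = sfrac;
        int ph;
        if (S.loaded[leg]) ph = (S.loaded[1 - leg] && S.last_hs[1 - leg] > S.last_hs[leg]) ? 1 : 0;
        else ph = (sfrac > 0.85 || (!S.loaded[leg] && (S.time() - S.last_to[leg]) > 0.7 * 0.38 * S.stride_T)) ? 3 : 2;
          traj(irec, 29 + leg) = ph;
      }
      traj(irec, 31) = S.belt_now[0]; traj(irec, 32) = S.belt_now[1];
      traj(irec, 33) = S.kinetic_energy();
      traj(irec, 34) = S.potential_energy();
      traj(irec, 35) = S.Emet;
      for (int gi = 0; gi < NM; gi++) {
        int b = 36 + 6 * gi;
        traj(irec, b) = S.a[gi]; traj(irec, b + 1) = S.stim[gi];
        traj(irec, b + 2) = S.lce[gi]; traj(irec, b + 3) = S.vce_ms[gi];
        traj(irec, b + 4) = S.Fse[gi]; traj(irec, b + 5) = S.lmtu_cur[gi];
      }
      irec++;
    }
    if (st == nsteps) break;
    S.dynamics_step(foot_pts);
    // snapshot capture at heel strike
    if (snap_want && !snap_taken) {
      for (size_t e = ev_mark; e < S.ev_t.size(); e++) {
        if (S.ev_type[e] == 0 && S.ev_leg[e] == snap_leg && S.ev_t[e] >= snap_after) {
          snap_taken = 1;
          // serialize
          NumericVector q0(NQ), qd0(NQ), a0(NM), lc(NM), an(4), lh(2), ph(2), lt(2), ws(2);
          IntegerVector ao(4), ld(2);
          for (int i = 0; i < NQ; i++) { q0[i] = S.q[i]; qd0[i] = S.qd[i]; }
          for (int i = 0; i < NM; i++) { a0[i] = S.a[i]; lc[i] = S.lce[i]; }
          for (int i = 0; i < 4; i++) { an[i] = S.anchor[i]; ao[i] = S.anchor_on[i]; }
          for (int i = 0; i < 2; i++) {
            lh[i] = S.last_hs[i]; ph[i] = S.prev_hs[i]; lt[i] = S.last_to[i];
            ws[i] = S.wst[i]; ld[i] = S.loaded[i];
          }
          long nrest = std::min<long>(S.buf_count, S.nbuf);
          NumericMatrix bm(Sim::NSIG, (int)nrest);
          for (long k = S.buf_count - nrest; k < S.buf_count; k++)
            for (int sg = 0; sg < Sim::NSIG; sg++)
              bm(sg, (int)(k - (S.buf_count - nrest))) = S.bufat(sg, k);
          snap_out = List::create(
            _["t"] = S.time(), _["q"] = q0, _["qd"] = qd0, _["a"] = a0, _["lce"] = lc,
            _["anchor"] = an, _["anchor_on"] = ao, _["loaded"] = ld,
            _["last_hs"] = lh, _["prev_hs"] = ph, _["last_to"] = lt, _["wst"] = ws,
            _["stride_T"] = S.stride_T, _["buffers"] = bm,
            _["buf_count"] = (double)S.buf_count, _["dt"] = S.dt);
        }
      }
    }
    ev_mark = S.ev_t.size();
    // fall check
    int bad = S.blown;
    for (int i = 0; i < NQ; i++) if (!std::isfinite(S.q[i]) || !std::isfinite(S.qd[i])) bad = 1;
    if (bad || (S.contact_on && S.g > 0 && S.q[1] < S.fall_frac * S.hip0)) {
      fall = 1; fall_t = S.time();
      break;
    }
  }
  if (irec < nrec) traj = traj(Range(0, std::max<long>(irec - 1, 0)), _);

  // events table
  int nev = (int)S.ev_t.size();
  NumericVector evt(nev); IntegerVector evl(nev), evy(nev);
  for (int i = 0; i < nev; i++) { evt[i] = S.ev_t[i]; evl[i] = S.ev_leg[i]; evy[i] = S.ev_type[i]; }

  // final snapshot (always)
  NumericVector q0(NQ), qd0(NQ), a0(NM), lc(NM), an(4), lh(2), phv(2), lt(2), ws(2);
  IntegerVector ao(4), ld(2);
  for (int i = 0; i < NQ; i++) { q0[i] = S.q[i]; qd0[i] = S.qd[i]; }
  for (int i = 0; i < NM; i++) { a0[i] = S.a[i]; lc[i] = S.lce[i]; }
  for (int i = 0; i < 4; i++) { an[i] = S.anchor[i]; ao[i] = S.anchor_on[i]; }
  for (int i = 0; i < 2; i++) {
    lh[i] = S.last_hs[i]; phv[i] = S.prev_hs[i]; lt[i] = S.last_to[i];
    ws[i] = S.wst[i]; ld[i] = S.loaded[i];
  }
  long nrest = std::min<long>(S.buf_count, S.nbuf);
  NumericMatrix bm(Sim::NSIG, (int)std::max<long>(nrest, 1));
  for (long k = S.buf_count - nrest; k < S.buf_count; k++)
    for (int sg = 0; sg < Sim::NSIG; sg++)
      bm(sg, (int)(k - (S.buf_count - nrest))) = S.bufat(sg, k);
  List final_snap = List::create(
    _["t"] = S.time(), _["q"] = q0, _["qd"] = qd0, _["a"] = a0, _["lce"] = lc,
    _["anchor"] = an, _["anchor_on"] = ao, _["loaded"] = ld,
    _["last_hs"] = lh, _["prev_hs"] = phv, _["last_to"] = lt, _["wst"] = ws,
    _["stride_T"] = S.stride_T, _["buffers"] = bm,
    _["buf_count"] = (double)S.buf_count, _["dt"] = S.dt);

  List dinfo = List::create(
    _["tr_dl"] = NumericVector::create(S.tr_dl[0], S.tr_dl[1]),
    _["tr_capped"] = S.tr_capped,
    _["sr_qcap"] = S.sr_qcap,
    _["slip_hs_time"] = S.slip_hs_time,
    _["slip_onset"] = S.slip_t_onset,
    _["trip_hit"] = S.blk_hit,
    _["trip_hit_time"] = S.blk_hit_t,
    _["block_x"] = S.blk_xs);

  return List::create(
    _["traj"] = traj,
    _["events_t"] = evt, _["events_leg"] = evl, _["events_type"] = evy,
    _["fall"] = fall, _["fall_time"] = fall_t,
    _["distance"] = S.q[0] - S.x_start,
    _["duration_done"] = S.time() - S.t0_time,
    _["energy"] = S.Emet,
    _["t_start"] = S.t0_time,
    _["stride_T"] = S.stride_T,
    _["snapshot"] = snap_out,
    _["final"] = final_snap,
    _["disturb_info"] = dinfo);
}

// single-muscle force law (exported surface for the muscle_force operation)
// [[Rcpp::export]]
List rg_muscle_force_cpp(double act, double lce, double vrel,
                         double Fmax, double lopt, double vmax) {
  (void)vmax;
  double fl = f_l(lce, lopt), fv = f_v(vrel);
  double active = act * Fmax * fl * fv;
  double passive = Fmax * f_pe(lce, lopt) - Fmax * f_be(lce, lopt);
  double total = active + passive;
  if (total < 0) total = 0;
  return List::create(_["force"] = total, _["active"] = active,
                      _["passive"] = passive, _["f_l"] = fl, _["f_v"] = fv);
}

// MTU length and signed moment arms at given joint angles (hip, knee, ankle)
// [[Rcpp::export]]
List rg_mtu_geom_cpp(NumericVector th, NumericVector geom,
                     double lopt, double lslack) {
  MuscleDef md;
  md.lopt = lopt; md.lslack = lslack; md.Fmax = 1; md.vmax = 1; md.delay_steps = 0;
  for (int j = 0; j < 3; j++) {
    md.mode[j] = (int)geom[4 * j];
    md.r[j] = geom[4 * j + 1];
    md.thmax[j] = geom[4 * j + 2];
    md.thref[j] = geom[4 * j + 3];
  }
  double t3[3] = { th[0], th[1], th[2] };
  double l = Sim::mtu_len(md, t3);
  NumericVector arms(3);
  for (int j = 0; j < 3; j++) arms[j] = Sim::mtu_arm(md, j, t3[j]);
  return List::create(_["length"] = l, _["arms"] = arms);
}

// one reflex-network evaluation from explicit (already delayed) inputs
// [[Rcpp::export]]
NumericVector rg_control_cpp(NumericMatrix aff,  // 18 x 3 (F, L, V), legs stacked L then R
                             double lean, double leanrate,
                             NumericVector load, NumericVector w_st,
                             NumericVector ds, NumericVector swfrac,
                             NumericVector knee, NumericVector kneed,
                             SEXP params) {
  Sim S;
  parse_control(S, params);
  double A[NMUS][3][2];
  for (int leg = 0; leg < 2; leg++)
    for (int m = 0; m < NMUS; m++)
      for (int s = 0; s < 3; s++)
        A[m][s][leg] = aff(m + NMUS * leg, s);
  double out[NM];
  double loads[2] = { load[0], load[1] }, wsts[2] = { w_st[0], w_st[1] };
  double dss[2] = { ds[0], ds[1] }, sws[2] = { swfrac[0], swfrac[1] };
  double kn[2] = { knee[0], knee[1] }, knd[2] = { kneed[0], kneed[1] };
  Sim::control_law(S.cp, A, lean, leanrate, loads, wsts, dss, sws, kn, knd, out);
  NumericVector res(NM);
  for (int i = 0; i < NM; i++) res[i] = out[i];
  return res;
}
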