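#include <Rcpp.h>
#include <vector>
#include <cmath>
using namespace Rcpp;

// Piecewise-linear interpolation with constant extrapolation at both ends.
static double interp1(const std::vector<double>& x, const std::vector<double>& y,
                      double xi) {
  const int n = (int)x.size();
  if (xi <= x[0]) return y[0];
  if (xi >= x[n - 1]) return y[n - 1];
  int i = 1;
  while (x[i] < xi) ++i;
  const double w = (xi - x[i - 1]) / (x[i] - x[i - 1]);
  return y[i - 1] + w * (y[i] - y[i - 1]);
}

static double clamp01(double v) {
  return v < 0.0 ? 0.0 : (v > 1.0 ? 1.0 : v);
}

// Daily winter-wheat season loop.
//
// weather: matrix with columns radiation, tmin, tmax, precip, et0 (one row per
// day starting at emergence). The update order within a day is
// phenology -> soil water -> growth -> leaf senescence, and the run stops at
// DVS = 2 (maturity) or when weather is exhausted. Leaf biomass is carried in
// daily cohorts (mass, leaf area, physiological age); a cohort dies once its
// age, accumulated at max(0, Tmean)/35 per day, exceeds SPAN. Dead leaves stay
// in AGB; roots do not count towards AGB.
// [[Rcpp::export]]
List cpp_run_season(NumericMatrix weather, List crop, List soil, List policy,
                    double sm_init) {
  const int n = weather.nrow();

  const double tsum1 = as<double>(crop["tsum1"]);
  const double tsum2 = as<double>(crop["tsum2"]);
  const double tdwi  = as<double>(crop["tdwi"]);
  const double span  = as<double>(crop["span"]);
  const double sla   = as<double>(crop["sla"]);
  const double rgrlai = as<double>(crop["rgrlai"]);
  const double kext  = as<double>(crop["k_ext"]);
  const double eps   = as<double>(crop["eps_lue"]);
  const double rm_leaf = as<double>(crop["rm_leaf"]);
  const double rm_stem = as<double>(crop["rm_stem"]);
  const double rm_storage = as<double>(crop["rm_storage"]);
  const double rm_root = as<double>(crop["rm_root"]);
  const double q10   = as<double>(crop["q10"]);
  const double tbase = as<double>(crop["tbase_pheno"]);
  const double dvs_juv = as<double>(crop["dvs_juvenile"]);
  std::vector<double> pdvs = as<std::vector<double> >(crop["part_dvs"]);
  std::vector<double> pleaf = as<std::vector<double> >(crop["part_leaf"]);
  std::vector<double> pstem = as<std::vector<double> >(crop["part_stem"]);
  std::vector<double> pstor = as<std::vector<double> >(crop["part_storage"]);
  std::vector<double> proot = as<std::vector<double> >(crop["part_root"]);

  const double sm_wilt = as<double>(soil["sm_wilt"]);
  const double sm_fc   = as<double>(soil["sm_fc"]);
  const double sm_sat  = as<double>(soil["sm_sat"]);
  const double rd      = as<double>(soil["root_depth"]);
  const double critf   = as<double>(soil["sm_crit_frac"]);
  const double sm_crit = sm_wilt + critf * (sm_fc - sm_wilt);

  const bool irr_on = as<bool>(policy["enabled"]);
  const double smc  = as<double>(policy["SMc"]);
  const double vdep = as<double>(policy["V"]);

  // initial state: TDWI split by the DVS=0 partition fractions
  const double fl0 = interp1(pdvs, pleaf, 0.0);
  const double fs0 = interp1(pdvs, pstem, 0.0);
  const double fo0 = interp1(pdvs, pstor, 0.0);
  std::vector<double> coh_mass, coh_area, coh_age;
  coh_mass.push_back(tdwi * fl0);
  coh_area.push_back(sla * tdwi * fl0);
  coh_age.push_back(0.0);
  double stem = tdwi * fs0, storage = tdwi * fo0;
  double root = tdwi * (1.0 - fl0 - fs0 - fo0);
  double dead_leaf = 0.0;
  double lai = sla * tdwi * fl0;
  double sm = sm_init, tsum = 0.0;

  NumericVector o_dvs(n), o_tsum(n), o_lai(n), o_agb(n), o_twso(n), o_sm(n),
      o_irr(n), o_stress(n), o_leaf_living(n), o_leaf_dead(n), o_stem(n),
      o_root(n);
  int anth = NA_INTEGER, matu = NA_INTEGER;
  int last = n;

  for (int i = 0; i < n; ++i) {
    const double rad = weather(i, 0), tmin = weather(i, 1),
                 tmax = weather(i, 2), prec = weather(i, 3),
                 et0 = weather(i, 4);
    const double tmean = 0.5 * (tmin + tmax);

    // phenology
    const double dtsum = std::max(0.0, tmean - tbase);
    tsum += dtsum;
    double dvs = tsum <= tsum1 ? tsum / tsum1 : 1.0 + (tsum - tsum1) / tsum2;
    if (dvs > 2.0) dvs = 2.0;

    // soil water balance (bucket over the root zone, cm units for depth)
    double irr = 0.0;
    if (irr_on && sm < smc) {
      irr = vdep;
      sm += vdep / rd;
    }
    sm += prec / (10.0 * rd);
    const double stress = clamp01((sm - sm_wilt) / (sm_crit - sm_wilt));
    const double cover = 1.0 - std::exp(-kext * lai);
    const double eta = et0 * std::min(1.0, cover) * stress;
    sm -= eta / (10.0 * rd);
    if (sm > sm_sat) sm = sm_sat;
    if (sm < 0.5 * sm_wilt) sm = 0.5 * sm_wilt;

    // growth: light-use-efficiency assimilation, Q10 maintenance respiration
    double liv_leaf = 0.0;
    for (size_t k = 0; k < coh_mass.size(); ++k) liv_leaf += coh_mass[k];
    const double A = eps * 0.5 * rad * (1.0 - std::exp(-kext * lai)) * stress;
    double rm = (rm_leaf * liv_leaf + rm_stem * stem + rm_storage * storage +
                 rm_root * root) * std::pow(q10, (tmean - 25.0) / 10.0);
    if (rm > A) rm = A;
    const double net = A - rm;
    const double fl = interp1(pdvs, pleaf, dvs), fs = interp1(pdvs, pstem, dvs),
                 fo = interp1(pdvs, pstor, dvs), fr = interp1(pdvs, proot, dvs);
    const double dleaf = net * fl;
    stem += net * fs;
    storage += net * fo;
    root += net * fr;
    double dlai;
    if (dvs < dvs_juv) {
      dlai = std::min(lai * (std::exp(rgrlai * dtsum) - 1.0), sla * dleaf);
    } else {
      dlai = sla * dleaf;
    }
    if (dleaf > 0.0 || dlai > 0.0) {
      coh_mass.push_back(dleaf);
      coh_area.push_back(dlai);
      coh_age.push_back(0.0);
    }

    // senescence: physiological aging normalized to 35 degC
    const double aging = std::max(0.0, tmean) / 35.0;
    std::vector<double> nm, na, ng;
    for (size_t k = 0; k < coh_mass.size(); ++k) {
      const double age = coh_age[k] + aging;
      if (age > span) {
        dead_leaf += coh_mass[k];
      } else {
        nm.push_back(coh_mass[k]);
        na.push_back(coh_area[k]);
        ng.push_back(age);
      }
    }
    coh_mass.swap(nm);
    coh_area.swap(na);
    coh_age.swap(ng);
    liv_leaf = 0.0;
    lai = 0.0;
    for (size_t k = 0; k < coh_mass.size(); ++k) {
      liv_leaf += coh_mass[k];
      lai += coh_area[k];
    }

    o_dvs[i] = dvs;
    o_tsum[i] = tsum;
    o_lai[i] = lai;
    o_agb[i] = liv_leaf + dead_leaf + stem + storage;
    o_twso[i] = storage;
    o_sm[i] = sm;
    o_irr[i] = irr;
    o_stress[i] = stress;
    o_leaf_living[i] = liv_leaf;
    o_leaf_dead[i] = dead_leaf;
    o_stem[i] = stem;
    o_root[i] = root;

    if (anth == NA_INTEGER && dvs >= 1.0) anth = i + 1;
    if (dvs >= 2.0) {
      matu = i + 1;
      last = i + 1;
      break;
    }
  }

  if (last < n) {
    Range r(0, last - 1);
    o_dvs = o_dvs[r]; o_tsum = o_tsum[r]; o_lai = o_lai[r]; o_agb = o_agb[r];
    o_twso = o_twso[r]; o_sm = o_sm[r]; o_irr = o_irr[r];
    o_stress = o_stress[r]; o_leaf_living = o_leaf_living[r];
    o_leaf_dead = o_leaf_dead[r]; o_stem = o_stem[r]; o_root = o_root[r];
  }

  return List::create(
      _["dvs"] = o_dvs, _["tsum"] = o_tsum, _["lai"] = o_lai,
      _["agb"] = o_agb, _["twso"] = o_twso, _["sm"] = o_sm,
      _["irrigation"] = o_irr, _["stress"] = o_stress,
      _["leaf_living"] = o_leaf_living, _["leaf_dead"] = o_leaf_dead,
      _["stem"] = o_stem, _["root"] = o_root,
      _["anthesis_day"] = anth, _["maturity_day"] = matu,
      _["truncated"] = (matu == NA_INTEGER));
}
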