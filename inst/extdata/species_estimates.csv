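# Published quantitative-genetic and demographic parameter estimates (point
# estimate and standard error; se = 0 means no SE was published and the
# parameter is treated as fixed).
# r_max: intrinsic growth rate (per year).  T: generation time, years.
# Gf: direct additive genetic variance of female lay-date (days^2).
# Gi: indirect (male partner) additive genetic variance (days^2).
# Gfi: direct-indirect additive genetic covariance (days^2).
# Social plasticity is back-calculated as psi = Gfi / Gi.
species,r_max,T_mean,T_se,Gf_mean,Gf_se,Gi_mean,Gi_se,Gfi_mean,Gfi_se
common_gull,0.12,3.4,0,4.52,1.20,1.49,0.3,-1.380,0.590
great_tit,0.49,1.8,0.01,5.96,0.94,1.57,0.68,1.011,0.583
song_sparrow,0.77,1.0,0,12.30,0.370,3.60,1.40,6.588,0.00
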