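# default_reduced_v1 -- committed parameter set for the reduced clock model.
#
# Provenance: hand-tuned by the package authors to place the wild-type
# network on a limit cycle and to reproduce the qualitative genotype
# ladder (Cry1 KO short / WT / Chrono KO long; Cry1,Cry2 dKO damped via
# the CHRONO channel; triple KO arrhythmic), then calibrated to a
# wild-type period of 23.8 h by exact uniform time rescaling of all rate
# constants.  Exact numbers are an artifact decision, not measurements.
#
# Units (by prefix): v_*, basal_*, oe_* are conc/h; K_* are conc;
# kon* are 1/(conc.h); all other rate constants (dm_*, dp_*, dn_*, da_*,
# ktl_*, koff*, kimp) are 1/h.  Concentrations in arbitrary units.
#
# E-box transcription: basal + v * A_free / (K_tx + A_free)
# Bmal1 transcription: v_bmal * K_rev / (K_rev + [REV])
#
# CRY1 complexes are the strong/slow repressor channel (lower koff, lower
# degradation); CRY2 and CHRONO channels are weak/fast.  Chrono mRNA decay
# is tied to dm_per2 (same symbol) in the model builder and therefore has
# no entry here.

# transcription, conc/h
v_per1: 1.344614099
v_per2: 1.344614099
v_cry1: 0.2399319008
v_cry2:  0.46440538
v_chrono: 0.4798638016
v_rev: 1.199659504
v_bmal: 0.4163664314

# basal (activator-independent) transcription, conc/h
basal_per1: 0.01599546006
basal_per2: 0.01599546006
basal_cry1: 0.04798638016
basal_cry2: 0.09597276032
basal_chrono: 0.01599546006
basal_rev: 0.01599546006
basal_bmal:           0

# activation / repression constants, conc
K_tx: 0.1503794318
K_rev: 0.05913889892

# mRNA degradation, 1/h
dm_per1: 0.1824686388
dm_per2: 0.2027429319
dm_cry1: 0.07592386988
dm_cry2: 0.07592386988
dm_rev: 0.7997730026
dm_bmal: 0.7997730026

# translation, 1/h
ktl_per: 0.2522848037
ktl_cry1: 1.174095339
ktl_cry2: 1.174095339
ktl_chrono: 0.7997730026
ktl_rev: 0.4663053099
ktl_bmal: 0.4663053099

# free-protein degradation, 1/h
dp_per: 0.08406401636
dp_cry1: 0.1236214783
dp_cry2: 0.1854322174
dp_chrono: 0.2225186609
dp_rev: 0.6398184021
dp_a: 0.1944383836

# cytoplasmic PER-partner binding, kon 1/(conc.h), koff 1/h
kon_pc: 8.467687275
koff_pc1: 0.08649145003
koff_pc2: 0.2594743501
koff_chr: 0.285421785

# nuclear import of PER-bound complexes (shared rate), 1/h
kimp: 0.1832267187

# nuclear repressor-pool degradation, 1/h
dn_pc1: 0.01514766346
dn_pc2: 0.04544299038
dn_chr: 0.04998728942

# activator sequestration, kona 1/(conc.h), koffa 1/h
kona: 39.98865013
koffa1: 0.003672757349
koffa2: 0.01101827205
koffa_chr: 0.01212009925

# repressor degradation inside activator complexes (releases A), 1/h
da_pc1: 0.02435302467
da_pc2: 0.07305907402
da_chr: 0.08036498142

# constitutive overexpression defaults, conc/h (about 2x the wild-type
# mean production flux of the target protein; configurable per run)
oe_per1:   1.3344966
oe_per2: 1.201262889
oe_cry1: 4.063903157
oe_cry2: 7.962834758
oe_chrono: 1.441154171
oe_rev: 0.5097304175
oe_bmal: 0.09390803631
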