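# Baseline + single follow-up, common outcome prevalence (40% reference vs
# 55% active on treatment), deviation in the active arm only.
row = 1
followups = 1
missing = 30
both_arms = FALSE
truth = MAR,CR
methods = mvn_rounding,latent
assumptions = MAR,CR
n_sim = 200
K = 50
burn_in = 500
thin = 500
n_true = 1000000
seed = 1
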