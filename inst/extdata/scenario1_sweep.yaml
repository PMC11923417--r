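# Example sweep configuration for `equivcurve simulate --config ...`
# Scenario-1 benchmark: null deviations, correct vs averaged specification.
scenario: 1
level_params: [0.75, 0.5, 0.25]     # true d = 1, 1.25, 1.5
sigma2_pairs: [[0.25, 0.25], [0.5, 0.5]]
n_pairs: [[20, 20], [50, 50]]
specifications: ["true", "ma_bic", "exp_exp"]
n_sim: 200
n_boot: 300
ci: hybrid
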