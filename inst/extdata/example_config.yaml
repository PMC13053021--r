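# Example pipeline configuration (see ?run_config / ?read_run_config).
# Coefficients are on the log-odds scale of P(overinformative upgrade);
# omit them to use the package defaults for the chosen experiment.
experiment: exp1
seed: 1
n_subjects: 72
sigma_u: 0.8
underinform_rate: 0.01
n_fatigue: 0
chains: 4
iter: 2000
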