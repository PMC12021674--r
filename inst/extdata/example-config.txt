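# Example configuration: keys follow the documented dotted schema
# (see ?load_config and param_keys()); unset keys keep package defaults.
colotect.cost: 65
colotect.compliance: 0.90
fit.sensitivity: 0.73
procedure.bleeding_basis: per_polypectomy
model.discount_rate: 0.035
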