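# Default synaptic weight magnitudes for the heart-rate state machines.
# Wiring probabilities come from the architecture parameter blocks; these
# magnitudes are free parameters of this implementation, found by the
# documented tuning procedure (see the methods vignette): grid search over a
# mean-field-guided region until, across network realization seeds at 20%
# device mismatch, (i) a stimulated band wins and remains selected, (ii) in
# the gated machines an un-gated band cannot ignite from input alone, (iii)
# gated adjacent transitions succeed at task-scale input rates, and (iv) no
# spontaneous gate-driven drift occurs while the winner is driven.
# Units: membrane-threshold units per presynaptic spike, at the stated
# slow (100 ms) and fast (10 ms) synaptic time constants.
wta:
  w_input: 0.08
  w_ee: 0.05
  w_ei: 0.70
  w_ie: -2.00
  w_ii: -0.10
nnnsm:
  w_input: 0.08
  w_ee: 0.05
  w_ei: 0.36
  w_ie: -2.00
  w_ii: -0.10
  w_ed: 0.04
  w_de: 0.06
  w_dee: 0.02
  w_dei: 1.00
  w_die: -2.00
  w_dii: -0.10
mononsm:
  w_input: 0.08
  w_ee: 0.08
  w_ei: 0.36
  w_ie: -2.00
  w_ii: -0.10
  w_ed: 0.04
  w_de: 0.03
  w_dee: 0.02
  w_dei: 1.00
  w_die: -2.00
  w_dii: -0.10
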