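# Reference kinetic parameters for sFLT1 secretion by HUVEC:
# component-wise medians of the accepted multistart fits of the
# maturation-delay model (M2) to constitutive and pulse-chase time courses.
model_id: M2
alpha: 1.419e5    # production rate, #/cell/h
beta: 5.123e-2    # secretion rate constant, 1/h
gamma: 1.215e-1   # intracellular degradation rate constant, 1/h
delta: 5.743e-2   # extracellular degradation rate constant, 1/h
tau: 1.958        # maturation delay, h
epsilon: 0.0      # internalization absent in M2
kappa: 0.0        # production decay absent in M2
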