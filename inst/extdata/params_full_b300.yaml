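# Production-scale parameter set: stiff chain in the moderate-attraction
# regime where film-like toroids form.
n_bonds: 300
b: 300.0
eps_a: 4.0
l_min: 0.4
l_max: 1.0
l0: 0.7
k_spring: 20.0
alpha: 24.0
r_min_ev: 0.8
eps_ev: 1.0
alpha_s: 24.0
r_min_s: 0.8
pair_cutoff: 1.0
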