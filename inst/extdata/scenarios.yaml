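# Default variant scenarios: per-variant colonization parameters for the
# synthetic study generator. phi = field colonization probability,
# p = within-field cell occupancy, rho = lateral column persistence,
# alpha/nu/sigma = arbuscule/vesicle/spore shares among occupied cells.
# Trajectories rise to the B3/B4 phenophases and fall at maturity (B5),
# with treated (A2) plants lagging untreated (A1) ones.
A0_B1: {phi: 0.747, p: 0.426, rho: 0.7, alpha: 0.286, nu: 0.0061, sigma: 0.005}
A1_B2: {phi: 0.609, p: 0.296, rho: 0.7, alpha: 0.188, nu: 0.0088, sigma: 0.005}
A1_B3: {phi: 0.764, p: 0.461, rho: 0.7, alpha: 0.204, nu: 0.0050, sigma: 0.005}
A1_B4: {phi: 0.774, p: 0.405, rho: 0.7, alpha: 0.202, nu: 0.0212, sigma: 0.005}
A1_B5: {phi: 0.627, p: 0.301, rho: 0.7, alpha: 0.100, nu: 0.0253, sigma: 0.005}
A2_B2: {phi: 0.525, p: 0.272, rho: 0.7, alpha: 0.086, nu: 0.0029, sigma: 0.005}
A2_B3: {phi: 0.717, p: 0.404, rho: 0.7, alpha: 0.137, nu: 0.0030, sigma: 0.005}
A2_B4: {phi: 0.681, p: 0.346, rho: 0.7, alpha: 0.153, nu: 0.0237, sigma: 0.005}
A2_B5: {phi: 0.509, p: 0.261, rho: 0.7, alpha: 0.164, nu: 0.0092, sigma: 0.005}
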