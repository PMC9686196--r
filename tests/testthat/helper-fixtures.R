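# Shared fixtures, built once per test run.

lat_au <- lattice_spec()

np_small <- build_wulff_nanoparticle(lat_au, wulff_spec(0.96, 2.0))
np_mid <- build_wulff_nanoparticle(lat_au, wulff_spec(1.2, 3.0))

# cheap quadrature for tests that only need qualitative areas
opt_fast <- sasa_options(quadrature_points = 240)

small_traj <- function(seed = 7, alpha = 1, n = 10, frames = 120,
                       spo = 8, box = 9, p0 = 0.05, agg = 0.8,
                       stride = 30, particle = np_small, ...) {
  simulate_adsorption(adsorption_params(
    particle, n_oligomers = n, box_edge = box, n_frames = frames,
    sites_per_oligomer = spo, facet_affinity = alpha,
    base_binding_prob = p0, aggregation_radius = agg,
    record_stride = stride, seed = seed, ...))
}
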