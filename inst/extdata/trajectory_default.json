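{
  "atlas": "average-nfb-atlas-approx-v1",
  "comment": "Average nerve-fiber bundle trajectory atlas in the power-law form phi(r) = phi0 + b(phi0) * (r - r0)^c(phi0), disc-centred polar degrees, phi0 = disc-entry angle measured counter-clockwise from the nasal horizontal, fovea on the temporal side near 180 deg. Superior/inferior arcuate coefficient tables are tanh-form reconstructions of the published average trajectories; across the nasal region (|phi0| < nasal_limit) the bundles taper smoothly to straight radial courses (synthetic interpolation, not a published table). Drop in a verbatim atlas by replacing this file.",
  "r0": 4.0,
  "variability_sd_deg": 6.0,
  "canonical_disc_xy_deg": [15.0, 2.0],
  "nasal_limit": 60.0,
  "nasal_taper_pow": 2.0,
  "superior": {
    "b": {"a0": -1.9, "a1": 3.9, "center": 121.0, "width": 14.0, "sign": 1},
    "c": {"c0": 1.9, "c1": 1.4, "center": 121.0, "width": 14.0}
  },
  "inferior": {
    "b": {"a0": 0.7, "a1": 1.5, "center": 90.0, "width": 25.0, "sign": -1},
    "c": {"c0": 1.0, "c1": 0.5, "center": 90.0, "width": 25.0}
  }
}
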