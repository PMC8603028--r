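# Generated by scripts/calibrate-surface-weights.R — do not edit by hand.
# Area contribution (voxel^2) per canonical 2x2x2 boundary-cell class;
# "edge3"/"sheet3" are the context split of the 2-adjacent-corner class
# (sharp 90-degree edge chains vs 45-degree sheets). The quad class (flat
# axis-aligned interface) is fixed at exactly 1; the rest were fit by
# nonnegative least squares on digitized balls, cubes, boxes, cylinders
# and ellipsoids with analytic surface areas.
surface_calibration_weights <- function() {
  c(`1` = 1.00678, `3` = 0, `6` = 0, `7` = 0.13427, `15` = 1, `22` = 0, `23` = 0, `24` = 0, `25` = 0, `27` = 0, `30` = 0, `60` = 0, `105` = 0, `edge3` = 0.891032, `sheet3` = 0.606635)
}
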