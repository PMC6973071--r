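# Idealized planar nucleobase templates (MMFF-optimized, plane-projected).
# Frame: glycosidic N at origin, x-axis toward C1' (marked C1X), base in z=0 plane.
.base_templates <- list(
  G = matrix(c(
    1.4385, -0.0000, 0.0000,
    0.0000, -0.0000, 0.0000,
    -0.8147, 1.1020, 0.0000,
    -2.0915, 0.7721, 0.0000,
    -2.0869, -0.6006, 0.0000,
    -0.8044, -1.1015, 0.0000,
    -0.4055, -2.3959, 0.0000,
    -1.4026, -3.2392, 0.0000,
    -1.1592, -4.5744, 0.0000,
    -2.7311, -2.8633, 0.0000,
    -3.1790, -1.5488, 0.0000,
    -4.3743, -1.2717, 0.0000,
    -0.4304, 2.1140, 0.0000,
    -0.1844, -4.7769, 0.0000,
    -1.7908, -5.1437, 0.0000,
    -3.4535, -3.5605, 0.0000
  ), ncol = 3, byrow = TRUE, dimnames = list(c("C1X", "N9", "C8", "N7", "C5", "C4", "N3", "C2", "N2", "N1", "C6", "O6", "H8", "H21", "H22", "H1"), c("x","y","z"))),
  A = matrix(c(
    1.4384, -0.0000, 0.0000,
    0.0000, -0.0000, 0.0000,
    -0.8149, 1.0983, 0.0000,
    -2.0891, 0.7637, 0.0000,
    -2.0898, -0.6183, 0.0000,
    -3.1241, -1.5690, 0.0000,
    -4.4712, -1.2286, 0.0000,
    -2.7958, -2.8813, 0.0000,
    -1.4858, -3.2142, 0.0000,
    -0.4118, -2.3982, 0.0000,
    -0.7948, -1.1111, 0.0000,
    -0.4338, 2.1119, 0.0000,
    -5.0502, -1.9712, 0.0000,
    -4.6454, -0.2850, 0.0000,
    -1.2717, -4.2793, 0.0000
  ), ncol = 3, byrow = TRUE, dimnames = list(c("C1X", "N9", "C8", "N7", "C5", "C6", "N6", "N1", "C2", "N3", "C4", "H8", "H61", "H62", "H2"), c("x","y","z"))),
  C = matrix(c(
    1.4528, 0.0000, 0.0000,
    0.0000, -0.0000, 0.0000,
    -0.6681, 1.2014, 0.0000,
    -1.9986, 1.2462, 0.0000,
    -2.6839, -0.0607, 0.0000,
    -4.0510, -0.1069, 0.0000,
    -2.0592, -1.1955, 0.0000,
    -0.6837, -1.2213, 0.0000,
    -0.0781, -2.2906, 0.0000,
    -0.0701, 2.1071, 0.0000,
    -2.5683, 2.1628, 0.0000,
    -4.5250, 0.6159, 0.0000,
    -4.3891, -1.0396, 0.0000
  ), ncol = 3, byrow = TRUE, dimnames = list(c("C1X", "N1", "C6", "C5", "C4", "N4", "N3", "C2", "O2", "H6", "H5", "H41", "H42"), c("x","y","z"))),
  T = matrix(c(
    1.4555, -0.0000, 0.0000,
    0.0000, 0.0000, 0.0000,
    -0.6610, 1.2110, 0.0000,
    -1.9964, 1.3011, 0.0000,
    -2.7575, 2.5853, 0.0000,
    -2.7769, 0.0412, 0.0000,
    -4.0032, 0.0388, 0.0000,
    -2.0485, -1.1126, 0.0000,
    -0.6822, -1.2095, 0.0000,
    -0.1433, -2.3138, 0.0000,
    -0.0379, 2.1016, 0.0000,
    -2.0893, 3.4530, 0.0000,
    -3.3928, 2.6554, 0.0000,
    -3.3928, 2.6554, 0.0000,
    -2.5609, -1.9799, 0.0000
  ), ncol = 3, byrow = TRUE, dimnames = list(c("C1X", "N1", "C6", "C5", "C7", "C4", "O4", "N3", "C2", "O2", "H6", "H71", "H72", "H73", "H3"), c("x","y","z")))
)
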