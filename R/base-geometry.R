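# Idealized planar-base nucleotide residue templates (standard chemical
# component geometry); coordinates Angstrom, one block per residue type.
# Used by the synthetic scene/aptamer generators, never by analyses.
BASE_TEMPLATES <- list(
  A = list(
    atom_name = c("O5'", "C5'", "C4'", "O4'", "C3'", "O3'", "C2'", "O2'", "C1'", "N9", "C8", "N7", "C5", "C6", "N6", "N1", "C2", "N3", "C4", "H5'", "H5''", "H4'", "H3'", "HO3'", "H2'", "HO2'", "H1'", "H8", "H61", "H62", "H2"),
    element = c("O", "C", "C", "O", "C", "O", "C", "O", "C", "N", "C", "N", "C", "C", "N", "N", "C", "N", "C", "H", "H", "H", "H", "H", "H", "H", "H", "H", "H", "H", "H"),
    coords = matrix(c(
      0.456, -0.720, -3.334,
      -0.520, 0.209, -2.863,
      -1.101, -0.287, -1.538,
      -0.064, -0.383, -0.538,
      -2.105, 0.739, -0.969,
      -3.445, 0.360, -1.287,
      -1.874, 0.684, 0.558,
      -3.065, 0.271, 1.231,
      -0.755, -0.367, 0.729,
      0.158, 0.029, 1.803,
      1.265, 0.813, 1.672,
      1.843, 0.963, 2.828,
      1.143, 0.292, 3.773,
      1.290, 0.091, 5.156,
      2.344, 0.664, 5.846,
      0.391, -0.656, 5.787,
      -0.617, -1.206, 5.136,
      -0.792, -1.051, 3.841,
      0.056, -0.320, 3.126,
      -1.319, 0.301, -3.599,
      -0.052, 1.182, -2.712,
      -1.586, -1.254, -1.677,
      -1.890, 1.736, -1.353,
      -4.024, 1.035, -0.908,
      -1.543, 1.654, 0.930,
      -3.740, 0.936, 1.037,
      -1.185, -1.346, 0.940,
      1.611, 1.246, 0.745,
      2.432, 0.522, 6.801,
      2.996, 1.205, 5.374,
      -1.325, -1.807, 5.688
    ), ncol = 3, byrow = TRUE)),
  C = list(
    atom_name = c("O5'", "C5'", "C4'", "O4'", "C3'", "O3'", "C2'", "O2'", "C1'", "N1", "C2", "O2", "N3", "C4", "N4", "C5", "C6", "H5'", "H5''", "H4'", "H3'", "HO3'", "H2'", "HO2'", "H1'", "H41", "H42", "H5", "H6"),
    element = c("O", "C", "C", "O", "C", "O", "C", "O", "C", "N", "C", "O", "N", "C", "N", "C", "C", "H", "H", "H", "H", "H", "H", "H", "H", "H", "H", "H", "H"),
    coords = matrix(c(
      0.415, -0.733, -2.721,
      -0.546, 0.181, -2.193,
      -1.189, -0.419, -0.942,
      -0.190, -0.648, 0.076,
      -2.178, 0.583, -0.307,
      -3.518, 0.283, -0.703,
      -2.001, 0.373, 1.215,
      -3.228, -0.059, 1.806,
      -0.924, -0.729, 1.317,
      -0.036, -0.470, 2.453,
      0.652, 0.683, 2.514,
      0.529, 1.504, 1.620,
      1.467, 0.945, 3.535,
      1.620, 0.070, 4.520,
      2.464, 0.350, 5.569,
      0.916, -1.151, 4.483,
      0.087, -1.399, 3.442,
      -1.315, 0.371, -2.941,
      -0.052, 1.118, -1.933,
      -1.699, -1.350, -1.188,
      -1.917, 1.604, -0.586,
      -4.088, 0.939, -0.278,
      -1.653, 1.290, 1.689,
      -3.874, 0.644, 1.656,
      -1.392, -1.708, 1.418,
      2.950, 1.189, 5.590,
      2.571, -0.289, 6.290,
      1.030, -1.873, 5.278,
      -0.465, -2.326, 3.393
    ), ncol = 3, byrow = TRUE)),
  G = list(
    atom_name = c("O5'", "C5'", "C4'", "O4'", "C3'", "O3'", "C2'", "O2'", "C1'", "N9", "C8", "N7", "C5", "C6", "O6", "N1", "C2", "N2", "N3", "C4", "H5'", "H5''", "H4'", "H3'", "HO3'", "H2'", "HO2'", "H1'", "H8", "H1", "H21", "H22"),
    element = c("O", "C", "C", "O", "C", "O", "C", "O", "C", "N", "C", "N", "C", "C", "O", "N", "C", "N", "N", "C", "H", "H", "H", "H", "H", "H", "H", "H", "H", "H", "H", "H"),
    coords = matrix(c(
      -0.365, -0.780, 3.580,
      0.542, 0.217, 3.109,
      1.100, -0.200, 1.748,
      0.033, -0.318, 0.782,
      2.025, 0.898, 1.182,
      3.395, 0.582, 1.439,
      1.741, 0.884, -0.338,
      2.927, 0.560, -1.066,
      0.675, -0.220, -0.507,
      -0.297, 0.162, -1.534,
      -1.440, 0.880, -1.334,
      -2.066, 1.037, -2.464,
      -1.364, 0.431, -3.453,
      -1.556, 0.279, -4.846,
      -2.534, 0.755, -5.397,
      -0.626, -0.401, -5.551,
      0.459, -0.934, -4.923,
      1.384, -1.626, -5.664,
      0.649, -0.800, -3.630,
      -0.226, -0.134, -2.868,
      1.362, 0.327, 3.820,
      0.018, 1.168, 3.011,
      1.640, -1.144, 1.833,
      1.772, 1.868, 1.610,
      3.923, 1.300, 1.065,
      1.346, 1.847, -0.662,
      3.573, 1.254, -0.871,
      1.148, -1.167, -0.769,
      -1.776, 1.261, -0.381,
      -0.736, -0.518, -6.508,
      2.165, -2.007, -5.232,
      1.256, -1.736, -6.619
    ), ncol = 3, byrow = TRUE)),
  U = list(
    atom_name = c("O5'", "C5'", "C4'", "O4'", "C3'", "O3'", "C2'", "O2'", "C1'", "N1", "C2", "O2", "N3", "C4", "O4", "C5", "C6", "H5'", "H5''", "H4'", "H3'", "HO3'", "H2'", "HO2'", "H1'", "H3", "H5", "H6"),
    element = c("O", "C", "C", "O", "C", "O", "C", "O", "C", "N", "C", "O", "N", "C", "O", "C", "C", "H", "H", "H", "H", "H", "H", "H", "H", "H", "H", "H"),
    coords = matrix(c(
      -0.399, 0.736, -2.726,
      0.557, -0.182, -2.196,
      1.197, 0.415, -0.942,
      0.194, 0.645, 0.074,
      2.181, -0.588, -0.301,
      3.524, -0.288, -0.686,
      1.995, -0.383, 1.218,
      3.219, 0.046, 1.819,
      0.922, 0.723, 1.319,
      0.028, 0.464, 2.451,
      -0.690, -0.671, 2.486,
      -0.587, -1.474, 1.580,
      -1.515, -0.936, 3.517,
      -1.641, -0.055, 4.530,
      -2.391, -0.292, 5.460,
      -0.894, 1.146, 4.502,
      -0.070, 1.384, 3.459,
      1.329, -0.373, -2.942,
      0.060, -1.117, -1.940,
      1.712, 1.345, -1.185,
      1.923, -1.609, -0.583,
      4.094, -0.926, -0.234,
      1.643, -1.301, 1.688,
      3.865, -0.657, 1.671,
      1.392, 1.700, 1.423,
      -2.024, -1.762, 3.528,
      -0.982, 1.863, 5.305,
      0.507, 2.295, 3.421
    ), ncol = 3, byrow = TRUE))
)
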