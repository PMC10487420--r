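# Amino-acid internal-coordinate topology tables.
# Generated from ideal residue geometry (chemical component
# dictionary); regenerate with data-raw/gen_topology.py.
# nolint start
..aa_topology <- list(
  ALA = list(
    place = data.frame(
      name = c("N", "CA", "C", "O", "H", "CB", "HA", "HB1", "HB2", "HB3"),
      element = c("N", "C", "C", "O", "H", "C", "H", "H", "H", "H"),
      r1 = c("-C", "N", "CA", "C", "N", "CA", "CA", "CB", "CB", "CB"),
      r2 = c("-CA", "-C", "N", "CA", "-C", "C", "C", "CA", "CA", "CA"),
      r3 = c("-N", "-CA", "-C", "N", "-O", "N", "N", "N", "N", "N"),
      bond = c(1.3290, 1.4580, 1.5250, 1.2310, 1.0000, 1.5294, 1.0899, 1.0907, 1.0899, 1.0901),
      angle = c(116.2000, 121.7000, 111.2000, 120.8000, 119.0000, 109.4474, 109.5153, 109.4905, 109.4323, 109.5239),
      dkind = c("tor", "tor", "tor", "tor", "fixed", "fixed", "fixed", "fixed", "fixed", "fixed"),
      dvalue = c(0.0000, 0.0000, 0.0000, 180.0000, 180.0000, 120.0096, -120.0524, -59.9713, 59.9976, -179.9612),
      dtor = c("psi_prev", "omega_prev", "phi", "psi", NA_character_, NA_character_, NA_character_, NA_character_, NA_character_, NA_character_),
      stringsAsFactors = FALSE
    ),
    bonds = matrix(c("N","CA", "N","H", "CA","C", "CA","CB", "CA","HA", "C","O", "CB","HB1", "CB","HB2", "CB","HB3"), ncol = 2, byrow = TRUE),
    chis = list()
  ),
  ARG = list(
    place = data.frame(
      name = c("N", "CA", "C", "O", "H", "CB", "HA", "CG", "HB2", "HB3", "CD", "HG2", "HG3", "NE", "HD2", "HD3", "CZ", "HE", "NH1", "NH2", "HH11", "HH12", "HH21", "HH22"),
      element = c("N", "C", "C", "O", "H", "C", "H", "C", "H", "H", "C", "H", "H", "N", "H", "H", "C", "H", "N", "N", "H", "H", "H", "H"),
      r1 = c("-C", "N", "CA", "C", "N", "CA", "CA", "CB", "CB", "CB", "CG", "CG", "CG", "CD", "CD", "CD", "NE", "NE", "CZ", "CZ", "NH1", "NH1", "NH2", "NH2"),
      r2 = c("-CA", "-C", "N", "CA", "-C", "C", "C", "CA", "CA", "CA", "CB", "CB", "CB", "CG", "CG", "CG", "CD", "CD", "NE", "NE", "CZ", "CZ", "CZ", "CZ"),
      r3 = c("-N", "-CA", "-C", "N", "-O", "N", "N", "N", "N", "N", "CA", "CA", "CA", "CB", "CB", "CB", "CG", "CG", "CD", "CD", "NE", "NE", "NE", "NE"),
      bond = c(1.3290, 1.4580, 1.5250, 1.2310, 1.0000, 1.5363, 1.0963, 1.5371, 1.0973, 1.0980, 1.5273, 1.0966, 1.0967, 1.4435, 1.0955, 1.0952, 1.4058, 1.0270, 1.3905, 1.3912, 1.0177, 1.0165, 1.0168, 1.0174),
      angle = c(116.2000, 121.7000, 111.2000, 120.8000, 119.0000, 111.9794, 107.9107, 114.5356, 108.9071, 108.8390, 112.4170, 109.5461, 110.0277, 111.0161, 109.4797, 110.6347, 123.0046, 120.4291, 120.9962, 119.8148, 120.9037, 121.9420, 121.2005, 121.1705),
      dkind = c("tor", "tor", "tor", "tor", "fixed", "fixed", "fixed", "tor", "tor", "tor", "tor", "tor", "tor", "tor", "tor", "tor", "tor", "tor", "fixed", "fixed", "fixed", "fixed", "fixed", "fixed"),
      dvalue = c(0.0000, 0.0000, 0.0000, 180.0000, 180.0000, 123.3008, -116.0672, 0.0000, -122.4150, 122.1245, 0.0000, -120.0966, 122.3820, 0.0000, 119.8157, -121.9377, 0.0000, -179.8288, 179.9864, -0.0124, -179.9595, 0.1979, 0.0564, 179.9065),
      dtor = c("psi_prev", "omega_prev", "phi", "psi", NA_character_, NA_character_, NA_character_, "chi1", "chi1", "chi1", "chi2", "chi2", "chi2", "chi3", "chi3", "chi3", "chi4", "chi4", NA_character_, NA_character_, NA_character_, NA_character_, NA_character_, NA_character_),
      stringsAsFactors = FALSE
    ),
    bonds = matrix(c("N","CA", "N","H", "CA","C", "CA","CB", "CA","HA", "C","O", "CB","CG", "CB","HB2", "CB","HB3", "CG","CD", "CG","HG2", "CG","HG3", "CD","NE", "CD","HD2", "CD","HD3", "NE","CZ", "NE","HE", "CZ","NH1", "CZ","NH2", "NH1","HH11", "NH1","HH12", "NH2","HH21", "NH2","HH22"), ncol = 2, byrow = TRUE),
    chis = list(
      chi1 = c("N", "CA", "CB", "CG"),
      chi2 = c("CA", "CB", "CG", "CD"),
      chi3 = c("CB", "CG", "CD", "NE"),
      chi4 = c("CG", "CD", "NE", "CZ")
    )
  ),
  ASN = list(
    place = data.frame(
      name = c("N", "CA", "C", "O", "H", "CB", "HA", "CG", "HB2", "HB3", "OD1", "ND2", "HD21", "HD22"),
      element = c("N", "C", "C", "O", "H", "C", "H", "C", "H", "H", "O", "N", "H", "H"),
      r1 = c("-C", "N", "CA", "C", "N", "CA", "CA", "CB", "CB", "CB", "CG", "CG", "ND2", "ND2"),
      r2 = c("-CA", "-C", "N", "CA", "-C", "C", "C", "CA", "CA", "CA", "CB", "CB", "CG", "CG"),
      r3 = c("-N", "-CA", "-C", "N", "-O", "N", "N", "N", "N", "N", "CA", "CA", "CB", "CB"),
      bond = c(1.3290, 1.4580, 1.5250, 1.2310, 1.0000, 1.5309, 1.0899, 1.5066, 1.0903, 1.0895, 1.2133, 1.3476, 0.9701, 0.9696),
      angle = c(116.2000, 121.7000, 111.2000, 120.8000, 119.0000, 109.4556, 109.4843, 109.4843, 109.4142, 109.4697, 119.9743, 120.0120, 119.9863, 120.0576),
      dkind = c("tor", "tor", "tor", "tor", "fixed", "fixed", "fixed", "tor", "tor", "tor", "tor", "tor", "fixed", "fixed"),
      dvalue = c(0.0000, 0.0000, 0.0000, 180.0000, 180.0000, 119.9950, -120.0757, 0.0000, 119.9676, -120.0326, 0.0000, -179.9262, -0.0515, 179.9901),
      dtor = c("psi_prev", "omega_prev", "phi", "psi", NA_character_, NA_character_, NA_character_, "chi1", "chi1", "chi1", "chi2", "chi2", NA_character_, NA_character_),
      stringsAsFactors = FALSE
    ),
    bonds = matrix(c("N","CA", "N","H", "CA","C", "CA","CB", "CA","HA", "C","O", "CB","CG", "CB","HB2", "CB","HB3", "CG","OD1", "CG","ND2", "ND2","HD21", "ND2","HD22"), ncol = 2, byrow = TRUE),
    chis = list(
      chi1 = c("N", "CA", "CB", "CG"),
      chi2 = c("CA", "CB", "CG", "OD1")
    )
  ),
  ASP = list(
    place = data.frame(
      name = c("N", "CA", "C", "O", "H", "CB", "HA", "CG", "HB2", "HB3", "OD1", "OD2", "HD2"),
      element = c("N", "C", "C", "O", "H", "C", "H", "C", "H", "H", "O", "O", "H"),
      r1 = c("-C", "N", "CA", "C", "N", "CA", "CA", "CB", "CB", "CB", "CG", "CG", "OD2"),
      r2 = c("-CA", "-C", "N", "CA", "-C", "C", "C", "CA", "CA", "CA", "CB", "CB", "CG"),
      r3 = c("-N", "-CA", "-C", "N", "-O", "N", "N", "N", "N", "N", "CA", "CA", "CB"),
      bond = c(1.3290, 1.4580, 1.5250, 1.2310, 1.0000, 1.5301, 1.0902, 1.5075, 1.0898, 1.0901, 1.2080, 1.3415, 0.9664),
      angle = c(116.2000, 121.7000, 111.2000, 120.8000, 119.0000, 109.4716, 109.4118, 109.4630, 109.4853, 109.4853, 119.9590, 119.9993, 117.0276),
      dkind = c("tor", "tor", "tor", "tor", "fixed", "fixed", "fixed", "tor", "tor", "tor", "tor", "tor", "fixed"),
      dvalue = c(0.0000, 0.0000, 0.0000, 180.0000, 180.0000, 120.0162, -119.9949, 0.0000, 119.9593, -120.0111, 0.0000, -179.9359, 179.9933),
      dtor = c("psi_prev", "omega_prev", "phi", "psi", NA_character_, NA_character_, NA_character_, "chi1", "chi1", "chi1", "chi2", "chi2", NA_character_),
      stringsAsFactors = FALSE
    ),
    bonds = matrix(c("N","CA", "N","H", "CA","C", "CA","CB", "CA","HA", "C","O", "CB","CG", "CB","HB2", "CB","HB3", "CG","OD1", "CG","OD2", "OD2","HD2"), ncol = 2, byrow = TRUE),
    chis = list(
      chi1 = c("N", "CA", "CB", "CG"),
      chi2 = c("CA", "CB", "CG", "OD1")
    )
  ),
  CYS = list(
    place = data.frame(
      name = c("N", "CA", "C", "O", "H", "CB", "HA", "SG", "HB2", "HB3", "HG"),
      element = c("N", "C", "C", "O", "H", "C", "H", "S", "H", "H", "H"),
      r1 = c("-C", "N", "CA", "C", "N", "CA", "CA", "CB", "CB", "CB", "SG"),
      r2 = c("-CA", "-C", "N", "CA", "-C", "C", "C", "CA", "CA", "CA", "CB"),
      r3 = c("-N", "-CA", "-C", "N", "-O", "N", "N", "N", "N", "N", "CA"),
      bond = c(1.3290, 1.4580, 1.5250, 1.2310, 1.0000, 1.5285, 1.0897, 1.8141, 1.0901, 1.0896, 1.3444),
      angle = c(116.2000, 121.7000, 111.2000, 120.8000, 119.0000, 109.5112, 109.5036, 109.4981, 109.4724, 109.4416, 100.0342),
      dkind = c("tor", "tor", "tor", "tor", "fixed", "fixed", "fixed", "tor", "tor", "tor", "fixed"),
      dvalue = c(0.0000, 0.0000, 0.0000, 180.0000, 180.0000, 120.0043, -119.9110, 0.0000, 119.9825, -120.0181, -179.9618),
      dtor = c("psi_prev", "omega_prev", "phi", "psi", NA_character_, NA_character_, NA_character_, "chi1", "chi1", "chi1", NA_character_),
      stringsAsFactors = FALSE
    ),
    bonds = matrix(c("N","CA", "N","H", "CA","C", "CA","CB", "CA","HA", "C","O", "CB","SG", "CB","HB2", "CB","HB3", "SG","HG"), ncol = 2, byrow = TRUE),
    chis = list(
      chi1 = c("N", "CA", "CB", "SG")
    )
  ),
  GLN = list(
    place = data.frame(
      name = c("N", "CA", "C", "O", "H", "CB", "HA", "CG", "HB2", "HB3", "CD", "HG2", "HG3", "OE1", "NE2", "HE21", "HE22"),
      element = c("N", "C", "C", "O", "H", "C", "H", "C", "H", "H", "C", "H", "H", "O", "N", "H", "H"),
      r1 = c("-C", "N", "CA", "C", "N", "CA", "CA", "CB", "CB", "CB", "CG", "CG", "CG", "CD", "CD", "NE2", "NE2"),
      r2 = c("-CA", "-C", "N", "CA", "-C", "C", "C", "CA", "CA", "CA", "CB", "CB", "CB", "CG", "CG", "CD", "CD"),
      r3 = c("-N", "-CA", "-C", "N", "-O", "N", "N", "N", "N", "N", "CA", "CA", "CA", "CB", "CB", "CG", "CG"),
      bond = c(1.3290, 1.4580, 1.5250, 1.2310, 1.0000, 1.5288, 1.0896, 1.5284, 1.0906, 1.0896, 1.5066, 1.0906, 1.0896, 1.2122, 1.3471, 0.9694, 0.9704),
      angle = c(116.2000, 121.7000, 111.2000, 120.8000, 119.0000, 109.5405, 109.5110, 109.5344, 109.4211, 109.4409, 109.5426, 109.4595, 109.5022, 119.9367, 120.0933, 120.1198, 119.9555),
      dkind = c("tor", "tor", "tor", "tor", "fixed", "fixed", "fixed", "tor", "tor", "tor", "tor", "tor", "tor", "tor", "tor", "fixed", "fixed"),
      dvalue = c(0.0000, 0.0000, 0.0000, 180.0000, 180.0000, 120.0165, -119.9761, 0.0000, 119.9936, -120.1141, 0.0000, 119.9623, -120.0840, 0.0000, -179.9569, 179.9882, -0.0035),
      dtor = c("psi_prev", "omega_prev", "phi", "psi", NA_character_, NA_character_, NA_character_, "chi1", "chi1", "chi1", "chi2", "chi2", "chi2", "chi3", "chi3", NA_character_, NA_character_),
      stringsAsFactors = FALSE
    ),
    bonds = matrix(c("N","CA", "N","H", "CA","C", "CA","CB", "CA","HA", "C","O", "CB","CG", "CB","HB2", "CB","HB3", "CG","CD", "CG","HG2", "CG","HG3", "CD","OE1", "CD","NE2", "NE2","HE21", "NE2","HE22"), ncol = 2, byrow = TRUE),
    chis = list(
      chi1 = c("N", "CA", "CB", "CG"),
      chi2 = c("CA", "CB", "CG", "CD"),
      chi3 = c("CB", "CG", "CD", "OE1")
    )
  ),
  GLU = list(
    place = data.frame(
      name = c("N", "CA", "C", "O", "H", "CB", "HA", "CG", "HB2", "HB3", "CD", "HG2", "HG3", "OE1", "OE2", "HE2"),
      element = c("N", "C", "C", "O", "H", "C", "H", "C", "H", "H", "C", "H", "H", "O", "O", "H"),
      r1 = c("-C", "N", "CA", "C", "N", "CA", "CA", "CB", "CB", "CB", "CG", "CG", "CG", "CD", "CD", "OE2"),
      r2 = c("-CA", "-C", "N", "CA", "-C", "C", "C", "CA", "CA", "CA", "CB", "CB", "CB", "CG", "CG", "CD"),
      r3 = c("-N", "-CA", "-C", "N", "-O", "N", "N", "N", "N", "N", "CA", "CA", "CA", "CB", "CB", "CG"),
      bond = c(1.3290, 1.4580, 1.5250, 1.2310, 1.0000, 1.5302, 1.0897, 1.5306, 1.0901, 1.0891, 1.5076, 1.0901, 1.0894, 1.2084, 1.3425, 0.9663),
      angle = c(116.2000, 121.7000, 111.2000, 120.8000, 119.0000, 109.4279, 109.4560, 109.4016, 109.5095, 109.5036, 109.4303, 109.5026, 109.4463, 120.0030, 119.9977, 116.9918),
      dkind = c("tor", "tor", "tor", "tor", "fixed", "fixed", "fixed", "tor", "tor", "tor", "tor", "tor", "tor", "tor", "tor", "fixed"),
      dvalue = c(0.0000, 0.0000, 0.0000, 180.0000, 180.0000, 119.9889, -120.0273, 0.0000, 119.9635, -119.9773, 0.0000, 119.9653, -119.9539, 0.0000, -179.9373, 179.9872),
      dtor = c("psi_prev", "omega_prev", "phi", "psi", NA_character_, NA_character_, NA_character_, "chi1", "chi1", "chi1", "chi2", "chi2", "chi2", "chi3", "chi3", NA_character_),
      stringsAsFactors = FALSE
    ),
    bonds = matrix(c("N","CA", "N","H", "CA","C", "CA","CB", "CA","HA", "C","O", "CB","CG", "CB","HB2", "CB","HB3", "CG","CD", "CG","HG2", "CG","HG3", "CD","OE1", "CD","OE2", "OE2","HE2"), ncol = 2, byrow = TRUE),
    chis = list(
      chi1 = c("N", "CA", "CB", "CG"),
      chi2 = c("CA", "CB", "CG", "CD"),
      chi3 = c("CB", "CG", "CD", "OE1")
    )
  ),
  GLY = list(
    place = data.frame(
      name = c("N", "CA", "C", "O", "H", "HA2", "HA3"),
      element = c("N", "C", "C", "O", "H", "H", "H"),
      r1 = c("-C", "N", "CA", "C", "N", "CA", "CA"),
      r2 = c("-CA", "-C", "N", "CA", "-C", "C", "C"),
      r3 = c("-N", "-CA", "-C", "N", "-O", "N", "N"),
      bond = c(1.3290, 1.4580, 1.5250, 1.2310, 1.0000, 1.0896, 1.0903),
      angle = c(116.2000, 121.7000, 111.2000, 120.8000, 119.0000, 109.4697, 109.4715),
      dkind = c("tor", "tor", "tor", "tor", "fixed", "fixed", "fixed"),
      dvalue = c(0.0000, 0.0000, 0.0000, 180.0000, 180.0000, -119.9935, 119.9548),
      dtor = c("psi_prev", "omega_prev", "phi", "psi", NA_character_, NA_character_, NA_character_),
      stringsAsFactors = FALSE
    ),
    bonds = matrix(c("N","CA", "N","H", "CA","C", "CA","HA2", "CA","HA3", "C","O"), ncol = 2, byrow = TRUE),
    chis = list()
  ),
  HIS = list(
    place = data.frame(
      name = c("N", "CA", "C", "O", "H", "CB", "HA", "CG", "HB2", "HB3", "ND1", "CD2", "CE1", "HD1", "NE2", "HD2", "HE1", "HE2"),
      element = c("N", "C", "C", "O", "H", "C", "H", "C", "H", "H", "N", "C", "C", "H", "N", "H", "H", "H"),
      r1 = c("-C", "N", "CA", "C", "N", "CA", "CA", "CB", "CB", "CB", "CG", "CG", "ND1", "ND1", "CD2", "CD2", "CE1", "NE2"),
      r2 = c("-CA", "-C", "N", "CA", "-C", "C", "C", "CA", "CA", "CA", "CB", "CB", "CG", "CG", "CG", "CG", "ND1", "CD2"),
      r3 = c("-N", "-CA", "-C", "N", "-O", "N", "N", "N", "N", "N", "CA", "CA", "CB", "CB", "CB", "CB", "CG", "CG"),
      bond = c(1.3290, 1.4580, 1.5250, 1.2310, 1.0000, 1.5337, 1.0958, 1.5100, 1.0987, 1.0982, 1.3513, 1.3376, 1.3369, 1.0163, 1.3739, 1.0723, 1.0777, 1.0156),
      angle = c(116.2000, 121.7000, 111.2000, 120.8000, 119.0000, 109.9372, 106.8813, 112.9791, 110.3817, 110.1994, 120.3285, 129.9283, 107.8621, 127.0804, 105.3318, 137.1496, 126.1756, 125.4757),
      dkind = c("tor", "tor", "tor", "tor", "fixed", "fixed", "fixed", "tor", "tor", "tor", "tor", "tor", "fixed", "fixed", "fixed", "fixed", "fixed", "fixed"),
      dvalue = c(0.0000, 0.0000, 0.0000, 180.0000, 180.0000, 123.4614, -115.5277, 0.0000, 121.1196, -123.0905, 0.0000, 179.8457, 179.9049, -0.0840, -179.8641, -0.0225, 179.9914, 179.9347),
      dtor = c("psi_prev", "omega_prev", "phi", "psi", NA_character_, NA_character_, NA_character_, "chi1", "chi1", "chi1", "chi2", "chi2", NA_character_, NA_character_, NA_character_, NA_character_, NA_character_, NA_character_),
      stringsAsFactors = FALSE
    ),
    bonds = matrix(c("N","CA", "N","H", "CA","C", "CA","CB", "CA","HA", "C","O", "CB","CG", "CB","HB2", "CB","HB3", "CG","ND1", "CG","CD2", "ND1","CE1", "ND1","HD1", "CD2","NE2", "CD2","HD2", "CE1","NE2", "CE1","HE1", "NE2","HE2"), ncol = 2, byrow = TRUE),
    chis = list(
      chi1 = c("N", "CA", "CB", "CG"),
      chi2 = c("CA", "CB", "CG", "ND1")
    )
  ),
  ILE = list(
    place = data.frame(
      name = c("N", "CA", "C", "O", "H", "CB", "HA", "CG1", "CG2", "HB", "CD1", "HG12", "HG13", "HG21", "HG22", "HG23", "HD11", "HD12", "HD13"),
      element = c("N", "C", "C", "O", "H", "C", "H", "C", "C", "H", "C", "H", "H", "H", "H", "H", "H", "H", "H"),
      r1 = c("-C", "N", "CA", "C", "N", "CA", "CA", "CB", "CB", "CB", "CG1", "CG1", "CG1", "CG2", "CG2", "CG2", "CD1", "CD1", "CD1"),
      r2 = c("-CA", "-C", "N", "CA", "-C", "C", "C", "CA", "CA", "CA", "CB", "CB", "CB", "CB", "CB", "CB", "CG1", "CG1", "CG1"),
      r3 = c("-N", "-CA", "-C", "N", "-O", "N", "N", "N", "N", "N", "CA", "CA", "CA", "CA", "CA", "CA", "CB", "CB", "CB"),
      bond = c(1.3290, 1.4580, 1.5250, 1.2310, 1.0000, 1.5288, 1.0907, 1.5294, 1.5303, 1.0893, 1.5288, 1.0898, 1.0895, 1.0885, 1.0900, 1.0898, 1.0891, 1.0903, 1.0897),
      angle = c(116.2000, 121.7000, 111.2000, 120.8000, 119.0000, 109.5456, 109.4306, 109.5474, 109.4577, 109.4848, 109.5474, 109.4338, 109.4756, 109.4850, 109.4497, 109.4798, 109.6037, 109.4936, 109.4579),
      dkind = c("tor", "tor", "tor", "tor", "fixed", "fixed", "fixed", "tor", "tor", "tor", "tor", "tor", "tor", "fixed", "fixed", "fixed", "fixed", "fixed", "fixed"),
      dvalue = c(0.0000, 0.0000, 0.0000, 180.0000, 180.0000, 120.0026, -120.0151, 0.0000, -119.9719, 120.0904, 0.0000, -119.9715, 120.0331, 59.9726, -179.9483, -60.0297, -179.9919, -59.9014, 59.9796),
      dtor = c("psi_prev", "omega_prev", "phi", "psi", NA_character_, NA_character_, NA_character_, "chi1", "chi1", "chi1", "chi2", "chi2", "chi2", NA_character_, NA_character_, NA_character_, NA_character_, NA_character_, NA_character_),
      stringsAsFactors = FALSE
    ),
    bonds = matrix(c("N","CA", "N","H", "CA","C", "CA","CB", "CA","HA", "C","O", "CB","CG1", "CB","CG2", "CB","HB", "CG1","CD1", "CG1","HG12", "CG1","HG13", "CG2","HG21", "CG2","HG22", "CG2","HG23", "CD1","HD11", "CD1","HD12", "CD1","HD13"), ncol = 2, byrow = TRUE),
    chis = list(
      chi1 = c("N", "CA", "CB", "CG1"),
      chi2 = c("CA", "CB", "CG1", "CD1")
    )
  ),
  LEU = list(
    place = data.frame(
      name = c("N", "CA", "C", "O", "H", "CB", "HA", "CG", "HB2", "HB3", "CD1", "CD2", "HG", "HD11", "HD12", "HD13", "HD21", "HD22", "HD23"),
      element = c("N", "C", "C", "O", "H", "C", "H", "C", "H", "H", "C", "C", "H", "H", "H", "H", "H", "H", "H"),
      r1 = c("-C", "N", "CA", "C", "N", "CA", "CA", "CB", "CB", "CB", "CG", "CG", "CG", "CD1", "CD1", "CD1", "CD2", "CD2", "CD2"),
      r2 = c("-CA", "-C", "N", "CA", "-C", "C", "C", "CA", "CA", "CA", "CB", "CB", "CB", "CG", "CG", "CG", "CG", "CG", "CG"),
      r3 = c("-N", "-CA", "-C", "N", "-O", "N", "N", "N", "N", "N", "CA", "CA", "CA", "CB", "CB", "CB", "CB", "CB", "CB"),
      bond = c(1.3290, 1.4580, 1.5250, 1.2310, 1.0000, 1.5286, 1.0895, 1.5303, 1.0898, 1.0902, 1.5300, 1.5285, 1.0896, 1.0892, 1.0903, 1.0898, 1.0898, 1.0899, 1.0903),
      angle = c(116.2000, 121.7000, 111.2000, 120.8000, 119.0000, 109.4932, 109.5308, 109.4950, 109.4621, 109.5405, 109.5000, 109.5008, 109.4031, 109.4929, 109.5083, 109.4476, 109.4268, 109.4971, 109.4847),
      dkind = c("tor", "tor", "tor", "tor", "fixed", "fixed", "fixed", "tor", "tor", "tor", "tor", "tor", "tor", "fixed", "fixed", "fixed", "fixed", "fixed", "fixed"),
      dvalue = c(0.0000, 0.0000, 0.0000, 180.0000, 180.0000, 119.9257, -120.0164, 0.0000, -119.9648, 120.0807, 0.0000, 120.0918, -119.8613, 179.9786, -59.8779, 60.0410, -60.0533, 59.9424, 179.9829),
      dtor = c("psi_prev", "omega_prev", "phi", "psi", NA_character_, NA_character_, NA_character_, "chi1", "chi1", "chi1", "chi2", "chi2", "chi2", NA_character_, NA_character_, NA_character_, NA_character_, NA_character_, NA_character_),
      stringsAsFactors = FALSE
    ),
    bonds = matrix(c("N","CA", "N","H", "CA","C", "CA","CB", "CA","HA", "C","O", "CB","CG", "CB","HB2", "CB","HB3", "CG","CD1", "CG","CD2", "CG","HG", "CD1","HD11", "CD1","HD12", "CD1","HD13", "CD2","HD21", "CD2","HD22", "CD2","HD23"), ncol = 2, byrow = TRUE),
    chis = list(
      chi1 = c("N", "CA", "CB", "CG"),
      chi2 = c("CA", "CB", "CG", "CD1")
    )
  ),
  LYS = list(
    place = data.frame(
      name = c("N", "CA", "C", "O", "H", "CB", "HA", "CG", "HB2", "HB3", "CD", "HG2", "HG3", "CE", "HD2", "HD3", "NZ", "HE2", "HE3", "HZ1", "HZ2", "HZ3"),
      element = c("N", "C", "C", "O", "H", "C", "H", "C", "H", "H", "C", "H", "H", "C", "H", "H", "N", "H", "H", "H", "H", "H"),
      r1 = c("-C", "N", "CA", "C", "N", "CA", "CA", "CB", "CB", "CB", "CG", "CG", "CG", "CD", "CD", "CD", "CE", "CE", "CE", "NZ", "NZ", "NZ"),
      r2 = c("-CA", "-C", "N", "CA", "-C", "C", "C", "CA", "CA", "CA", "CB", "CB", "CB", "CG", "CG", "CG", "CD", "CD", "CD", "CE", "CE", "CE"),
      r3 = c("-N", "-CA", "-C", "N", "-O", "N", "N", "N", "N", "N", "CA", "CA", "CA", "CB", "CB", "CB", "CG", "CG", "CG", "CD", "CD", "CD"),
      bond = c(1.3290, 1.4580, 1.5250, 1.2310, 1.0000, 1.5300, 1.0895, 1.5307, 1.0891, 1.0901, 1.5308, 1.0893, 1.0901, 1.5291, 1.0901, 1.0901, 1.4694, 1.0901, 1.0900, 1.0095, 1.0084, 1.0088),
      angle = c(116.2000, 121.7000, 111.2000, 120.8000, 119.0000, 109.4542, 109.4704, 109.4176, 109.5091, 109.4869, 109.4405, 109.4687, 109.4908, 109.4647, 109.5046, 109.4309, 109.5004, 109.5336, 109.5014, 109.3691, 109.4677, 109.5277),
      dkind = c("tor", "tor", "tor", "tor", "fixed", "fixed", "fixed", "tor", "tor", "tor", "tor", "tor", "tor", "tor", "tor", "tor", "tor", "tor", "tor", "fixed", "fixed", "fixed"),
      dvalue = c(0.0000, 0.0000, 0.0000, 180.0000, 180.0000, 119.9661, -119.9748, 0.0000, 120.0171, -119.9440, 0.0000, 119.9790, -119.9438, 0.0000, 120.0360, -119.9780, 0.0000, 119.9717, -120.0475, -60.0047, 59.9500, -179.9599),
      dtor = c("psi_prev", "omega_prev", "phi", "psi", NA_character_, NA_character_, NA_character_, "chi1", "chi1", "chi1", "chi2", "chi2", "chi2", "chi3", "chi3", "chi3", "chi4", "chi4", "chi4", NA_character_, NA_character_, NA_character_),
      stringsAsFactors = FALSE
    ),
    bonds = matrix(c("N","CA", "N","H", "CA","C", "CA","CB", "CA","HA", "C","O", "CB","CG", "CB","HB2", "CB","HB3", "CG","CD", "CG","HG2", "CG","HG3", "CD","CE", "CD","HD2", "CD","HD3", "CE","NZ", "CE","HE2", "CE","HE3", "NZ","HZ1", "NZ","HZ2", "NZ","HZ3"), ncol = 2, byrow = TRUE),
    chis = list(
      chi1 = c("N", "CA", "CB", "CG"),
      chi2 = c("CA", "CB", "CG", "CD"),
      chi3 = c("CB", "CG", "CD", "CE"),
      chi4 = c("CG", "CD", "CE", "NZ")
    )
  ),
  MET = list(
    place = data.frame(
      name = c("N", "CA", "C", "O", "H", "CB", "HA", "CG", "HB2", "HB3", "SD", "HG2", "HG3", "CE", "HE1", "HE2", "HE3"),
      element = c("N", "C", "C", "O", "H", "C", "H", "C", "H", "H", "S", "H", "H", "C", "H", "H", "H"),
      r1 = c("-C", "N", "CA", "C", "N", "CA", "CA", "CB", "CB", "CB", "CG", "CG", "CG", "SD", "CE", "CE", "CE"),
      r2 = c("-CA", "-C", "N", "CA", "-C", "C", "C", "CA", "CA", "CA", "CB", "CB", "CB", "CG", "SD", "SD", "SD"),
      r3 = c("-N", "-CA", "-C", "N", "-O", "N", "N", "N", "N", "N", "CA", "CA", "CA", "CB", "CG", "CG", "CG"),
      bond = c(1.3290, 1.4580, 1.5250, 1.2310, 1.0000, 1.5294, 1.0895, 1.5284, 1.0901, 1.0905, 1.8137, 1.0903, 1.0895, 1.8135, 1.0891, 1.0893, 1.0899),
      angle = c(116.2000, 121.7000, 111.2000, 120.8000, 119.0000, 109.5428, 109.4965, 109.5449, 109.4389, 109.4620, 109.5064, 109.4601, 109.4834, 100.0339, 109.5482, 109.4602, 109.4479),
      dkind = c("tor", "tor", "tor", "tor", "fixed", "fixed", "fixed", "tor", "tor", "tor", "tor", "tor", "tor", "tor", "fixed", "fixed", "fixed"),
      dvalue = c(0.0000, 0.0000, 0.0000, 180.0000, 180.0000, 119.9660, -119.9921, 0.0000, -120.0398, 120.0543, 0.0000, -119.9798, 120.0199, 0.0000, 179.9723, -60.0028, 60.0303),
      dtor = c("psi_prev", "omega_prev", "phi", "psi", NA_character_, NA_character_, NA_character_, "chi1", "chi1", "chi1", "chi2", "chi2", "chi2", "chi3", NA_character_, NA_character_, NA_character_),
      stringsAsFactors = FALSE
    ),
    bonds = matrix(c("N","CA", "N","H", "CA","C", "CA","CB", "CA","HA", "C","O", "CB","CG", "CB","HB2", "CB","HB3", "CG","SD", "CG","HG2", "CG","HG3", "SD","CE", "CE","HE1", "CE","HE2", "CE","HE3"), ncol = 2, byrow = TRUE),
    chis = list(
      chi1 = c("N", "CA", "CB", "CG"),
      chi2 = c("CA", "CB", "CG", "SD"),
      chi3 = c("CB", "CG", "SD", "CE")
    )
  ),
  PHE = list(
    place = data.frame(
      name = c("N", "CA", "C", "O", "H", "CB", "HA", "CG", "HB2", "HB3", "CD1", "CD2", "CE1", "HD1", "CE2", "HD2", "CZ", "HE1", "HE2", "HZ"),
      element = c("N", "C", "C", "O", "H", "C", "H", "C", "H", "H", "C", "C", "C", "H", "C", "H", "C", "H", "H", "H"),
      r1 = c("-C", "N", "CA", "C", "N", "CA", "CA", "CB", "CB", "CB", "CG", "CG", "CD1", "CD1", "CD2", "CD2", "CE1", "CE1", "CE2", "CZ"),
      r2 = c("-CA", "-C", "N", "CA", "-C", "C", "C", "CA", "CA", "CA", "CB", "CB", "CG", "CG", "CG", "CG", "CD1", "CD1", "CD2", "CE1"),
      r3 = c("-N", "-CA", "-C", "N", "-O", "N", "N", "N", "N", "N", "CA", "CA", "CB", "CB", "CB", "CB", "CG", "CG", "CG", "CD1"),
      bond = c(1.3290, 1.4580, 1.5250, 1.2310, 1.0000, 1.5289, 1.0896, 1.5052, 1.0905, 1.0897, 1.3817, 1.3832, 1.3820, 1.0801, 1.3819, 1.0801, 1.3806, 1.0802, 1.0809, 1.0800),
      angle = c(116.2000, 121.7000, 111.2000, 120.8000, 119.0000, 109.5362, 109.4445, 109.5165, 109.4435, 109.4924, 120.0585, 120.0047, 120.0292, 119.9524, 119.9770, 119.9717, 120.0469, 119.9773, 119.9333, 120.0736),
      dkind = c("tor", "tor", "tor", "tor", "fixed", "fixed", "fixed", "tor", "tor", "tor", "tor", "tor", "fixed", "fixed", "fixed", "fixed", "fixed", "fixed", "fixed", "fixed"),
      dvalue = c(0.0000, 0.0000, 0.0000, 180.0000, 180.0000, 120.0557, -119.9508, 0.0000, 120.0521, -120.0699, 0.0000, 179.7575, 179.9942, 0.0369, 179.8391, 0.1540, -0.0485, 179.9695, -179.7324, 179.9385),
      dtor = c("psi_prev", "omega_prev", "phi", "psi", NA_character_, NA_character_, NA_character_, "chi1", "chi1", "chi1", "chi2", "chi2", NA_character_, NA_character_, NA_character_, NA_character_, NA_character_, NA_character_, NA_character_, NA_character_),
      stringsAsFactors = FALSE
    ),
    bonds = matrix(c("N","CA", "N","H", "CA","C", "CA","CB", "CA","HA", "C","O", "CB","CG", "CB","HB2", "CB","HB3", "CG","CD1", "CG","CD2", "CD1","CE1", "CD1","HD1", "CD2","CE2", "CD2","HD2", "CE1","CZ", "CE1","HE1", "CE2","CZ", "CE2","HE2", "CZ","HZ"), ncol = 2, byrow = TRUE),
    chis = list(
      chi1 = c("N", "CA", "CB", "CG"),
      chi2 = c("CA", "CB", "CG", "CD1")
    )
  ),
  PRO = list(
    place = data.frame(
      name = c("N", "CA", "C", "O", "CB", "HA", "CG", "HB2", "HB3", "CD", "HG2", "HG3", "HD2", "HD3"),
      element = c("N", "C", "C", "O", "C", "H", "C", "H", "H", "C", "H", "H", "H", "H"),
      r1 = c("-C", "N", "CA", "C", "CA", "CA", "CB", "CB", "CB", "CG", "CG", "CG", "CD", "CD"),
      r2 = c("-CA", "-C", "N", "CA", "C", "C", "CA", "CA", "CA", "CB", "CB", "CB", "CG", "CG"),
      r3 = c("-N", "-CA", "-C", "N", "N", "N", "N", "N", "N", "CA", "CA", "CA", "CB", "CB"),
      bond = c(1.3290, 1.4580, 1.5250, 1.2310, 1.5434, 1.0899, 1.5426, 1.0903, 1.0895, 1.5437, 1.0900, 1.0904, 1.0903, 1.0899),
      angle = c(116.2000, 121.7000, 111.2000, 120.8000, 110.4143, 110.3622, 105.0594, 110.3550, 110.3543, 105.0631, 110.3647, 110.3653, 110.4601, 110.4192),
      dkind = c("tor", "tor", "tor", "tor", "fixed", "fixed", "fixed", "fixed", "fixed", "fixed", "fixed", "fixed", "fixed", "fixed"),
      dvalue = c(0.0000, 0.0000, 0.0000, 180.0000, 115.3135, -122.3133, -23.7996, 95.0178, -142.6888, 0.0255, 118.8608, -118.8610, 142.6493, -94.9126),
      dtor = c("psi_prev", "omega_prev", "phi", "psi", NA_character_, NA_character_, NA_character_, NA_character_, NA_character_, NA_character_, NA_character_, NA_character_, NA_character_, NA_character_),
      stringsAsFactors = FALSE
    ),
    bonds = matrix(c("N","CA", "N","CD", "N","H", "CA","C", "CA","CB", "CA","HA", "C","O", "CB","CG", "CB","HB2", "CB","HB3", "CG","CD", "CG","HG2", "CG","HG3", "CD","HD2", "CD","HD3"), ncol = 2, byrow = TRUE),
    chis = list()
  ),
  SER = list(
    place = data.frame(
      name = c("N", "CA", "C", "O", "H", "CB", "HA", "OG", "HB2", "HB3", "HG"),
      element = c("N", "C", "C", "O", "H", "C", "H", "O", "H", "H", "H"),
      r1 = c("-C", "N", "CA", "C", "N", "CA", "CA", "CB", "CB", "CB", "OG"),
      r2 = c("-CA", "-C", "N", "CA", "-C", "C", "C", "CA", "CA", "CA", "CB"),
      r3 = c("-N", "-CA", "-C", "N", "-O", "N", "N", "N", "N", "N", "CA"),
      bond = c(1.3290, 1.4580, 1.5250, 1.2310, 1.0000, 1.5287, 1.0897, 1.4283, 1.0902, 1.0896, 0.9670),
      angle = c(116.2000, 121.7000, 111.2000, 120.8000, 119.0000, 109.5059, 109.4835, 109.5115, 109.4341, 109.4805, 106.8145),
      dkind = c("tor", "tor", "tor", "tor", "fixed", "fixed", "fixed", "tor", "tor", "tor", "fixed"),
      dvalue = c(0.0000, 0.0000, 0.0000, 180.0000, 180.0000, 119.9991, -119.9320, 0.0000, 120.0069, -120.0365, -179.9690),
      dtor = c("psi_prev", "omega_prev", "phi", "psi", NA_character_, NA_character_, NA_character_, "chi1", "chi1", "chi1", NA_character_),
      stringsAsFactors = FALSE
    ),
    bonds = matrix(c("N","CA", "N","H", "CA","C", "CA","CB", "CA","HA", "C","O", "CB","OG", "CB","HB2", "CB","HB3", "OG","HG"), ncol = 2, byrow = TRUE),
    chis = list(
      chi1 = c("N", "CA", "CB", "OG")
    )
  ),
  THR = list(
    place = data.frame(
      name = c("N", "CA", "C", "O", "H", "CB", "HA", "OG1", "CG2", "HB", "HG1", "HG21", "HG22", "HG23"),
      element = c("N", "C", "C", "O", "H", "C", "H", "O", "C", "H", "H", "H", "H", "H"),
      r1 = c("-C", "N", "CA", "C", "N", "CA", "CA", "CB", "CB", "CB", "OG1", "CG2", "CG2", "CG2"),
      r2 = c("-CA", "-C", "N", "CA", "-C", "C", "C", "CA", "CA", "CA", "CB", "CB", "CB", "CB"),
      r3 = c("-N", "-CA", "-C", "N", "-O", "N", "N", "N", "N", "N", "CA", "CA", "CA", "CA"),
      bond = c(1.3290, 1.4580, 1.5250, 1.2310, 1.0000, 1.5290, 1.0898, 1.4280, 1.5301, 1.0898, 0.9666, 1.0893, 1.0901, 1.0888),
      angle = c(116.2000, 121.7000, 111.2000, 120.8000, 119.0000, 109.5324, 109.5309, 109.5053, 109.5255, 109.4276, 106.8126, 109.4779, 109.4679, 109.4591),
      dkind = c("tor", "tor", "tor", "tor", "fixed", "fixed", "fixed", "tor", "tor", "tor", "fixed", "fixed", "fixed", "fixed"),
      dvalue = c(0.0000, 0.0000, 0.0000, 180.0000, 180.0000, 119.9261, -119.9311, 0.0000, -120.0308, 119.9922, -60.0565, -179.9370, -59.9435, 60.0412),
      dtor = c("psi_prev", "omega_prev", "phi", "psi", NA_character_, NA_character_, NA_character_, "chi1", "chi1", "chi1", NA_character_, NA_character_, NA_character_, NA_character_),
      stringsAsFactors = FALSE
    ),
    bonds = matrix(c("N","CA", "N","H", "CA","C", "CA","CB", "CA","HA", "C","O", "CB","OG1", "CB","CG2", "CB","HB", "OG1","HG1", "CG2","HG21", "CG2","HG22", "CG2","HG23"), ncol = 2, byrow = TRUE),
    chis = list(
      chi1 = c("N", "CA", "CB", "OG1")
    )
  ),
  TRP = list(
    place = data.frame(
      name = c("N", "CA", "C", "O", "H", "CB", "HA", "CG", "HB2", "HB3", "CD1", "CD2", "NE1", "HD1", "CE2", "CE3", "HE1", "CZ2", "CZ3", "HE3", "CH2", "HZ2", "HZ3", "HH2"),
      element = c("N", "C", "C", "O", "H", "C", "H", "C", "H", "H", "C", "C", "N", "H", "C", "C", "H", "C", "C", "H", "C", "H", "H", "H"),
      r1 = c("-C", "N", "CA", "C", "N", "CA", "CA", "CB", "CB", "CB", "CG", "CG", "CD1", "CD1", "CD2", "CD2", "NE1", "CE2", "CE3", "CE3", "CZ2", "CZ2", "CZ3", "CH2"),
      r2 = c("-CA", "-C", "N", "CA", "-C", "C", "C", "CA", "CA", "CA", "CB", "CB", "CG", "CG", "CG", "CG", "CD1", "CD2", "CD2", "CD2", "CE2", "CE2", "CE3", "CZ2"),
      r3 = c("-N", "-CA", "-C", "N", "-O", "N", "N", "N", "N", "N", "CA", "CA", "CB", "CB", "CB", "CB", "CG", "CG", "CG", "CG", "CD2", "CD2", "CD2", "CE2"),
      bond = c(1.3290, 1.4580, 1.5250, 1.2310, 1.0000, 1.5286, 1.0899, 1.5067, 1.0899, 1.0895, 1.3426, 1.4639, 1.3686, 1.0792, 1.4068, 1.3961, 0.9691, 1.3906, 1.3659, 1.0802, 1.3773, 1.0805, 1.0799, 1.0800),
      angle = c(116.2000, 121.7000, 111.2000, 120.8000, 119.0000, 109.4878, 109.4395, 109.4419, 109.4702, 109.5124, 126.4957, 126.5119, 109.9318, 125.0894, 106.0764, 134.0470, 125.0687, 119.3458, 119.7952, 120.0708, 119.8063, 120.1130, 119.7562, 119.6414),
      dkind = c("tor", "tor", "tor", "tor", "fixed", "fixed", "fixed", "tor", "tor", "tor", "tor", "tor", "fixed", "fixed", "fixed", "fixed", "fixed", "fixed", "fixed", "fixed", "fixed", "fixed", "fixed", "fixed"),
      dvalue = c(0.0000, 0.0000, 0.0000, 180.0000, 180.0000, 120.0469, -119.9636, 0.0000, 119.9608, -119.9931, 0.0000, 179.6215, 179.9435, -0.0578, 179.9578, 0.7839, -179.9699, -179.8255, 179.6391, -0.6780, 0.2212, -179.8502, 179.6597, 179.9561),
      dtor = c("psi_prev", "omega_prev", "phi", "psi", NA_character_, NA_character_, NA_character_, "chi1", "chi1", "chi1", "chi2", "chi2", NA_character_, NA_character_, NA_character_, NA_character_, NA_character_, NA_character_, NA_character_, NA_character_, NA_character_, NA_character_, NA_character_, NA_character_),
      stringsAsFactors = FALSE
    ),
    bonds = matrix(c("N","CA", "N","H", "CA","C", "CA","CB", "CA","HA", "C","O", "CB","CG", "CB","HB2", "CB","HB3", "CG","CD1", "CG","CD2", "CD1","NE1", "CD1","HD1", "CD2","CE2", "CD2","CE3", "NE1","CE2", "NE1","HE1", "CE2","CZ2", "CE3","CZ3", "CE3","HE3", "CZ2","CH2", "CZ2","HZ2", "CZ3","CH2", "CZ3","HZ3", "CH2","HH2"), ncol = 2, byrow = TRUE),
    chis = list(
      chi1 = c("N", "CA", "CB", "CG"),
      chi2 = c("CA", "CB", "CG", "CD1")
    )
  ),
  TYR = list(
    place = data.frame(
      name = c("N", "CA", "C", "O", "H", "CB", "HA", "CG", "HB2", "HB3", "CD1", "CD2", "CE1", "HD1", "CE2", "HD2", "CZ", "HE1", "HE2", "OH", "HH"),
      element = c("N", "C", "C", "O", "H", "C", "H", "C", "H", "H", "C", "C", "C", "H", "C", "H", "C", "H", "H", "O", "H"),
      r1 = c("-C", "N", "CA", "C", "N", "CA", "CA", "CB", "CB", "CB", "CG", "CG", "CD1", "CD1", "CD2", "CD2", "CE1", "CE1", "CE2", "CZ", "OH"),
      r2 = c("-CA", "-C", "N", "CA", "-C", "C", "C", "CA", "CA", "CA", "CB", "CB", "CG", "CG", "CG", "CG", "CD1", "CD1", "CD2", "CE1", "CZ"),
      r3 = c("-N", "-CA", "-C", "N", "-O", "N", "N", "N", "N", "N", "CA", "CA", "CB", "CB", "CB", "CB", "CG", "CG", "CG", "CD1", "CE1"),
      bond = c(1.3290, 1.4580, 1.5250, 1.2310, 1.0000, 1.5287, 1.0907, 1.5062, 1.0893, 1.0909, 1.3823, 1.3830, 1.3810, 1.0793, 1.3809, 1.0795, 1.3867, 1.0795, 1.0800, 1.3582, 0.9664),
      angle = c(116.2000, 121.7000, 111.2000, 120.8000, 119.0000, 109.5062, 109.4862, 109.4975, 109.5118, 109.4603, 119.9470, 119.9427, 120.0729, 119.9415, 120.0203, 119.9964, 119.9781, 120.0572, 120.0442, 120.1300, 106.8813),
      dkind = c("tor", "tor", "tor", "tor", "fixed", "fixed", "fixed", "tor", "tor", "tor", "tor", "tor", "fixed", "fixed", "fixed", "fixed", "fixed", "fixed", "fixed", "fixed", "fixed"),
      dvalue = c(0.0000, 0.0000, 0.0000, 180.0000, 180.0000, 120.0190, -119.9548, 0.0000, 120.1033, -119.9886, 0.0000, 179.6919, -179.9763, 0.0277, 179.7745, 0.2438, -0.1021, 179.9540, -179.6602, -179.9660, 90.0400),
      dtor = c("psi_prev", "omega_prev", "phi", "psi", NA_character_, NA_character_, NA_character_, "chi1", "chi1", "chi1", "chi2", "chi2", NA_character_, NA_character_, NA_character_, NA_character_, NA_character_, NA_character_, NA_character_, NA_character_, NA_character_),
      stringsAsFactors = FALSE
    ),
    bonds = matrix(c("N","CA", "N","H", "CA","C", "CA","CB", "CA","HA", "C","O", "CB","CG", "CB","HB2", "CB","HB3", "CG","CD1", "CG","CD2", "CD1","CE1", "CD1","HD1", "CD2","CE2", "CD2","HD2", "CE1","CZ", "CE1","HE1", "CE2","CZ", "CE2","HE2", "CZ","OH", "OH","HH"), ncol = 2, byrow = TRUE),
    chis = list(
      chi1 = c("N", "CA", "CB", "CG"),
      chi2 = c("CA", "CB", "CG", "CD1")
    )
  ),
  VAL = list(
    place = data.frame(
      name = c("N", "CA", "C", "O", "H", "CB", "HA", "CG1", "CG2", "HB", "HG11", "HG12", "HG13", "HG21", "HG22", "HG23"),
      element = c("N", "C", "C", "O", "H", "C", "H", "C", "C", "H", "H", "H", "H", "H", "H", "H"),
      r1 = c("-C", "N", "CA", "C", "N", "CA", "CA", "CB", "CB", "CB", "CG1", "CG1", "CG1", "CG2", "CG2", "CG2"),
      r2 = c("-CA", "-C", "N", "CA", "-C", "C", "C", "CA", "CA", "CA", "CB", "CB", "CB", "CB", "CB", "CB"),
      r3 = c("-N", "-CA", "-C", "N", "-O", "N", "N", "N", "N", "N", "CA", "CA", "CA", "CA", "CA", "CA"),
      bond = c(1.3290, 1.4580, 1.5250, 1.2310, 1.0000, 1.5287, 1.0896, 1.5299, 1.5292, 1.0909, 1.0905, 1.0896, 1.0889, 1.0899, 1.0897, 1.0903),
      angle = c(116.2000, 121.7000, 111.2000, 120.8000, 119.0000, 109.4913, 109.4819, 109.5086, 109.4895, 109.4560, 109.5198, 109.4569, 109.4590, 109.4733, 109.4964, 109.5304),
      dkind = c("tor", "tor", "tor", "tor", "fixed", "fixed", "fixed", "tor", "tor", "tor", "fixed", "fixed", "fixed", "fixed", "fixed", "fixed"),
      dvalue = c(0.0000, 0.0000, 0.0000, 180.0000, 180.0000, 119.9755, -120.0006, 0.0000, 120.0257, -119.9712, -179.9893, -59.9808, 60.0332, -60.0212, 59.9747, 179.9528),
      dtor = c("psi_prev", "omega_prev", "phi", "psi", NA_character_, NA_character_, NA_character_, "chi1", "chi1", "chi1", NA_character_, NA_character_, NA_character_, NA_character_, NA_character_, NA_character_),
      stringsAsFactors = FALSE
    ),
    bonds = matrix(c("N","CA", "N","H", "CA","C", "CA","CB", "CA","HA", "C","O", "CB","CG1", "CB","CG2", "CB","HB", "CG1","HG11", "CG1","HG12", "CG1","HG13", "CG2","HG21", "CG2","HG22", "CG2","HG23"), ncol = 2, byrow = TRUE),
    chis = list(
      chi1 = c("N", "CA", "CB", "CG1")
    )
  )
)

..dialect_table <- data.frame(
  resname = c("*", "*", "ILE", "ARG", "ARG", "ARG", "ARG", "ARG", "ARG", "ASN", "ASN", "ASP", "ASP", "CYS", "CYS", "CYS", "GLN", "GLN", "GLN", "GLN", "GLU", "GLU", "GLU", "GLU", "GLY", "GLY", "HIS", "HIS", "ILE", "ILE", "LEU", "LEU", "LYS", "LYS", "LYS", "LYS", "LYS", "LYS", "LYS", "LYS", "MET", "MET", "MET", "MET", "PHE", "PHE", "PRO", "PRO", "PRO", "PRO", "PRO", "PRO", "SER", "SER", "SER", "TRP", "TRP", "TRP", "TRP", "TYR", "TYR", "ILE", "ILE", "ILE"),
  pdb3 = c("H", "OXT", "CD1", "HB2", "HB3", "HD2", "HD3", "HG2", "HG3", "HB2", "HB3", "HB2", "HB3", "HB2", "HB3", "HG", "HB2", "HB3", "HG2", "HG3", "HB2", "HB3", "HG2", "HG3", "HA2", "HA3", "HB2", "HB3", "HG12", "HG13", "HB2", "HB3", "HB2", "HB3", "HD2", "HD3", "HE2", "HE3", "HG2", "HG3", "HB2", "HB3", "HG2", "HG3", "HB2", "HB3", "HB2", "HB3", "HD2", "HD3", "HG2", "HG3", "HB2", "HB3", "HG", "HB2", "HB3", "HZ2", "HZ3", "HB2", "HB3", "HD11", "HD12", "HD13"),
  charmm = c("HN", "OT2", "CD", "HB1", "HB2", "HD1", "HD2", "HG1", "HG2", "HB1", "HB2", "HB1", "HB2", "HB1", "HB2", "HG1", "HB1", "HB2", "HG1", "HG2", "HB1", "HB2", "HG1", "HG2", "HA1", "HA2", "HB1", "HB2", "HG11", "HG12", "HB1", "HB2", "HB1", "HB2", "HD1", "HD2", "HE1", "HE2", "HG1", "HG2", "HB1", "HB2", "HG1", "HG2", "HB1", "HB2", "HB1", "HB2", "HD1", "HD2", "HG1", "HG2", "HB1", "HB2", "HG1", "HB1", "HB2", "HZ1", "HZ2", "HB1", "HB2", "HD1", "HD2", "HD3"),
  stringsAsFactors = FALSE
)
# nolint end
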