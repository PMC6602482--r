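# Fixtures and independent oracles shared across the suite. Everything is
# generated in code; no binary fixtures.

# build an antigen_structure directly from residue point sets
# pts: n x 3 matrix of C-alpha positions; atoms: optional list of
# per-residue atom coordinate matrices (defaults to the single CA)
toy_structure <- function(pts, aa = NULL, atoms = NULL, surface = TRUE,
                          rasa = NULL, pdb_id = "TOYS") {
  n <- nrow(pts)
  if (is.null(aa)) aa <- rep("A", n)
  if (is.null(atoms)) atoms <- lapply(seq_len(n), function(i) {
    matrix(pts[i, ], 1, 3)
  })
  at <- data.table::rbindlist(lapply(seq_len(n), function(i) {
    m <- atoms[[i]]
    data.table::data.table(
      res_index = i,
      name = c("CA", "CB", "CG", "CD", "CE", "CZ")[seq_len(nrow(m))],
      element = "C", x = m[, 1], y = m[, 2], z = m[, 3],
      altloc = " ", occupancy = 1.0)
  }))
  if (length(surface) == 1) surface <- rep(surface, n)
  if (is.null(rasa)) rasa <- ifelse(surface, 0.5, 0.05)
  res <- data.table::data.table(
    seq_id = seq_len(n), icode = " ", aa = aa,
    sasa = rasa * 100, rasa = rasa, is_surface = surface)
  structure(list(pdb_id = pdb_id, chain_id = "A", residues = res,
                 atoms = at, sequence = paste(aa, collapse = "")),
            class = "antigen_structure")
}

# random residue cloud with k atoms per residue, for oracle equivalence
random_cloud <- function(n, k = 1, box = 25, seed = 1, aa = NULL) {
  set.seed(seed)
  pts <- matrix(runif(n * 3, 0, box), n, 3)
  atoms <- lapply(seq_len(n), function(i) {
    m <- matrix(rnorm(3 * k, sd = 1.2), k, 3)
    sweep(m, 2, pts[i, ], `+`)
  })
  if (is.null(aa)) aa <- sample(strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]],
                                n, replace = TRUE)
  toy_structure(pts, aa = aa, atoms = atoms)
}

# a tiny hand-written PDB file: three residues (ALA, GLY, SER), chain A,
# plus a water and a chain-B residue, with one ALA altloc pair
toy_pdb_text <- function() {
  paste(c(
    "HEADER    TEST PROTEIN                            01-JAN-20   1TOY",
    "ATOM      1  N  AALA A   1       0.000   0.000   0.000  0.60  0.00           N",
    "ATOM      2  CA AALA A   1       1.400   0.000   0.000  0.60  0.00           C",
    "ATOM      3  N  BALA A   1       0.100   0.100   0.000  0.40  0.00           N",
    "ATOM      4  CA BALA A   1       1.500   0.100   0.000  0.40  0.00           C",
    "ATOM      5  H   ALA A   1       2.000   1.000   0.000  1.00  0.00           H",
    "ATOM      6  N   GLY A   2       4.000   0.000   0.000  1.00  0.00           N",
    "ATOM      7  CA  GLY A   2       5.400   0.000   0.000  1.00  0.00           C",
    "ATOM      8  N   SER A   3       8.000   0.000   0.000  1.00  0.00           N",
    "ATOM      9  CA  SER A   3       9.400   0.000   0.000  1.00  0.00           C",
    "HETATM   10  O   HOH A 101      20.000  20.000  20.000  1.00  0.00           O",
    "ATOM     11  CA  VAL B   1       0.000  10.000   0.000  1.00  0.00           C",
    "TER",
    "END"), collapse = "\n")
}

# O(n^3) brute-force triangle oracle over surface residues
brute_triangles <- function(struct, dmat, max_dist = 15) {
  surf <- which(struct$residues$is_surface)
  out <- list()
  if (length(surf) < 3) return(matrix(integer(0), 0, 3))
  combs <- utils::combn(surf, 3)
  keep <- apply(combs, 2, function(t3) {
    dmat[t3[1], t3[2]] <= max_dist && dmat[t3[1], t3[3]] <= max_dist &&
      dmat[t3[2], t3[3]] <= max_dist
  })
  t(combs[, keep, drop = FALSE])
}

triangle_key <- function(i, j, k) paste(i, j, k, sep = "/")

# pattern-matching sequon oracle (overlap-aware lookahead regex)
regex_sequons <- function(seq) {
  m <- gregexpr("N(?=[^P][ST])", seq, perl = TRUE)[[1]]
  if (m[1] == -1) integer(0) else as.integer(m)
}

# analytic area of a union of two spheres (radii r1, r2, center dist d)
two_sphere_union_area <- function(r1, r2, d) {
  if (d >= r1 + r2) return(4 * pi * (r1^2 + r2^2))
  if (d <= abs(r1 - r2)) return(4 * pi * max(r1, r2)^2)
  # spherical cap heights cut by the intersection plane
  x <- (d^2 - r2^2 + r1^2) / (2 * d)
  h1 <- r1 - x
  h2 <- r2 - (d - x)
  4 * pi * r1^2 - 2 * pi * r1 * h1 + 4 * pi * r2^2 - 2 * pi * r2 * h2
}

# concordant-pair AUC oracle
pairwise_auc <- function(scores, labels) {
  pos <- scores[as.logical(labels)]; neg <- scores[!as.logical(labels)]
  s <- 0
  for (p in pos) for (q in neg) s <- s + (p > q) + 0.5 * (p == q)
  s / (length(pos) * length(neg))
}

# small labeled corpus of toy structures for table arithmetic tests
# (see test-glyco.R for the hand-counted census)
rigid_transform <- function(struct, angle = 0.7, axis = c(1, 2, 3),
                            shift = c(10, -5, 3)) {
  axis <- axis / sqrt(sum(axis^2))
  K <- matrix(c(0, -axis[3], axis[2], axis[3], 0, -axis[1],
                -axis[2], axis[1], 0), 3, 3, byrow = TRUE)
  R <- diag(3) + sin(angle) * K + (1 - cos(angle)) * (K %*% K)
  st <- struct
  st$atoms <- data.table::copy(struct$atoms)
  st$residues <- data.table::copy(struct$residues)
  xyz <- as.matrix(st$atoms[, c("x", "y", "z")]) %*% t(R)
  xyz <- sweep(xyz, 2, shift, `+`)
  st$atoms[, c("x", "y", "z") := .(xyz[, 1], xyz[, 2], xyz[, 3])]
  st
}

# Hand-counted 5-structure corpus for the ratio-table arithmetic checks.
# Each structure has 4 single-atom surface residues on a 5 A square (all
# pairwise distances <= 15, so all C(4,3) = 4 triples are triangles).
# With the bundled subgroups (A,G=G01; V,L,I=G02; F=G03; Y=G04; W=G05;
# C=G06; M=G07; P=G08; S,T=G09; N,Q=G10; D,E=G11; K,R=G12; H=G13) the
# glytri census, counted by hand, is:
#   S1 "NASK" (sequon 1; epitopes 1,2): G01-G09-G10 1/1, G01-G10-G12 1/1,
#                                       G09-G10-G12 0/1
#   S2 "NCTA" (sequon 1; no epitopes):  G06-G09-G10 0/1, G01-G06-G10 0/1,
#                                       G01-G09-G10 0/1
#   S3 "NPSA" (NO sequon: proline X):   no glytri
#   S4 "ANAS" (sequon 2; epitopes 2,3,4): G01-G01-G10 1/1, G01-G09-G10 2/2
#   S5 "NTSW" (sequon 1; epitope 4):    G09-G09-G10 0/1, G05-G09-G10 0/2
# Pooled: G01-G01-G10 1/1; G01-G06-G10 0/1; G01-G09-G10 3/4;
#         G01-G10-G12 1/1; G05-G09-G10 0/2; G06-G09-G10 0/1;
#         G09-G09-G10 0/1; G09-G10-G12 0/1   (8 patterns)
make_tiny_corpus <- function() {
  sq <- matrix(c(0, 0, 0, 5, 0, 0, 0, 5, 0, 5, 5, 0), 4, 3, byrow = TRUE)
  mk <- function(id, seq4, epi) {
    st <- toy_structure(sq, aa = strsplit(seq4, "")[[1]], pdb_id = id)
    lab <- rep(FALSE, 4); lab[epi] <- TRUE
    labeling <- structure(
      list(structure_key = c(id, "A"), labels = lab,
           n_positive = sum(lab), n_negative_surface = sum(!lab)),
      class = "epitope_labeling")
    list(structure = st, labeling = labeling)
  }
  list(mk("TS01", "NASK", c(1, 2)),
       mk("TS02", "NCTA", integer(0)),
       mk("TS03", "NPSA", c(1, 2)),
       mk("TS04", "ANAS", c(2, 3, 4)),
       mk("TS05", "NTSW", 4))
}

tiny_corpus_expected_ratios <- function() {
  data.frame(
    pattern = c("G01-G01-G10", "G01-G06-G10", "G01-G09-G10",
                "G01-G10-G12", "G05-G09-G10", "G06-G09-G10",
                "G09-G09-G10", "G09-G10-G12"),
    n_epi_glytri = c(1L, 0L, 3L, 1L, 0L, 0L, 0L, 0L),
    n_glytri = c(1L, 1L, 4L, 1L, 2L, 1L, 1L, 1L),
    ratio = c(1, 0, 0.75, 1, 0, 0, 0, 0),
    stringsAsFactors = FALSE)
}
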