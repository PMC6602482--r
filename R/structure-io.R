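#' @import data.table
#' @importFrom stats rnorm runif sd quantile cov setNames complete.cases
#' @importFrom utils read.table capture.output
#' @importFrom tools file_path_sans_ext
NULL

# ---- residue / atom chemistry tables ------------------------------------

.AA3 <- c(
  ALA = "A", ARG = "R", ASN = "N", ASP = "D", CYS = "C", GLN = "Q",
  GLU = "E", GLY = "G", HIS = "H", ILE = "I", LEU = "L", LYS = "K",
  MET = "M", PHE = "F", PRO = "P", SER = "S", THR = "T", TRP = "W",
  TYR = "Y", VAL = "V"
)

# non-standard residues with a standard parent amino acid
.AA3_NONSTD <- c(
  MSE = "M", SEC = "C", CSO = "C", CME = "C", CSD = "C", OCS = "C",
  MLY = "K", KCX = "K", LLP = "K", HYP = "P", SEP = "S", TPO = "T",
  PTR = "Y", PCA = "E", CGU = "E", FME = "M", MLE = "L", DAL = "A",
  AIB = "A", NLE = "L"
)

.AA1 <- unname(.AA3)
names(.AA1) <- names(.AA3)

aa3_to_aa1 <- function(resname) {
  out <- .AA3[resname]
  miss <- is.na(out)
  if (any(miss)) out[miss] <- .AA3_NONSTD[resname[miss]]
  out
}

# Theoretical maximum solvent accessibility per residue type (Tien et al.
# 2013), used for relative SASA. 'X' falls back to the glycine value.
.MAX_SASA <- c(
  A = 129.0, R = 274.0, N = 195.0, D = 193.0, C = 167.0, Q = 225.0,
  E = 223.0, G = 104.0, H = 224.0, I = 197.0, L = 201.0, K = 236.0,
  M = 224.0, F = 240.0, P = 159.0, S = 155.0, T = 172.0, W = 285.0,
  Y = 263.0, V = 174.0
)

#' Maximum accessible surface per residue type
#'
#' Theoretical maximum solvent-accessible surface areas (Tien et al. 2013),
#' used to normalize per-residue SASA into relative SASA. Unknown residues
#' (`"X"`) use the glycine value.
#'
#' @return Named numeric vector (one-letter amino acid -> max SASA in
#'   square Angstrom).
#' @export
max_sasa_table <- function() .MAX_SASA

# van der Waals radii by element (A); default carbon-like for exotic elements
.VDW <- c(C = 1.70, N = 1.55, O = 1.52, S = 1.80, P = 1.80, SE = 1.90,
          F = 1.47, CL = 1.75, BR = 1.85, I = 1.98)

vdw_radius <- function(element) {
  r <- .VDW[toupper(element)]
  r[is.na(r)] <- 1.70
  unname(r)
}

# ---- PDB parsing ---------------------------------------------------------

pdb_lines <- function(input) {
  if (length(input) == 1L && !grepl("\n", input, fixed = TRUE) &&
      file.exists(input)) {
    return(readLines(input, warn = FALSE))
  }
  if (length(input) == 1L) return(strsplit(input, "\n", fixed = TRUE)[[1]])
  input
}

#' Parse a single chain from PDB-format text
#'
#' Reads ATOM/HETATM records of one chain from one model, keeps heavy atoms
#' only, maps non-standard residues to their parent amino acid (else `"X"`),
#' drops waters and unknown HETATM ligands, and resolves alternate locations
#' by keeping the highest-occupancy conformer per residue.
#'
#' @param input Path to a PDB file, a single string of PDB text, or a
#'   character vector of lines.
#' @param chain Chain identifier to extract.
#' @param model Model index (1-based) for multi-model files; default 1.
#' @param pdb_id Optional identifier; defaults to the HEADER id code or
#'   `"UNKN"`.
#' @return An `antigen_structure`: list with `pdb_id`, `chain_id`,
#'   `residues` (data.table: `seq_id`, `icode`, `aa`, `sasa`, `rasa`,
#'   `is_surface`), `atoms` (data.table: `res_index`, `name`, `element`,
#'   `x`, `y`, `z`, `altloc`, `occupancy`) and `sequence`.
#' @export
parse_pdb <- function(input, chain, model = 1L, pdb_id = NULL) {
  lines <- pdb_lines(input)
  rec <- substr(lines, 1, 6)

  # select requested MODEL block when present
  model_starts <- which(rec == "MODEL ")
  if (length(model_starts) > 0) {
    if (model > length(model_starts)) stop("model index out of range")
    from <- model_starts[model]
    ends <- which(rec == "ENDMDL")
    to <- ends[ends > from][1]
    if (is.na(to)) to <- length(lines)
    lines <- lines[from:to]
    rec <- substr(lines, 1, 6)
  }

  if (is.null(pdb_id)) {
    hd <- lines[rec == "HEADER"]
    pdb_id <- if (length(hd) && nchar(hd[1]) >= 66) {
      trimws(substr(hd[1], 63, 66))
    } else "UNKN"
    if (!nzchar(pdb_id)) pdb_id <- "UNKN"
  }

  is_atom <- rec == "ATOM  " | rec == "HETATM"
  al <- lines[is_atom]
  if (length(al) == 0) stop("chain not found: no atom records")

  chains <- substr(al, 22, 22)
  if (!any(chains == chain)) stop(sprintf("chain not found: '%s'", chain))
  al <- al[chains == chain]
  hrec <- substr(al, 1, 6) == "HETATM"

  name <- trimws(substr(al, 13, 16))
  altloc <- substr(al, 17, 17)
  resname <- trimws(substr(al, 18, 20))
  seq_id <- as.integer(substr(al, 23, 26))
  icode <- substr(al, 27, 27)
  x <- as.numeric(substr(al, 31, 38))
  y <- as.numeric(substr(al, 39, 46))
  z <- as.numeric(substr(al, 47, 54))
  occ <- suppressWarnings(as.numeric(substr(al, 55, 60)))
  occ[is.na(occ)] <- 1.0
  element <- toupper(trimws(substr(al, 77, 78)))
  # fall back to the atom-name convention when the element field is blank
  blank <- !nzchar(element)
  if (any(blank)) {
    guess <- substr(gsub("[0-9]", "", trimws(substr(al, 13, 16))), 1, 1)
    element[blank] <- toupper(guess[blank])
  }

  keep <- !(element %in% c("H", "D")) & !(resname %in% c("HOH", "WAT", "DOD"))
  aa <- aa3_to_aa1(resname)
  # unknown HETATM residues are ligands -> drop; unknown polymer residues -> X
  keep <- keep & !(hrec & is.na(aa))
  aa[is.na(aa)] <- "X"

  if (!any(keep)) stop("empty chain: no standard residues")
  idx <- which(keep)
  key <- paste(seq_id[idx], icode[idx], sep = "|")
  res_index <- match(key, unique(key))

  at <- data.table(
    res_index = res_index, name = name[idx], element = element[idx],
    x = x[idx], y = y[idx], z = z[idx],
    altloc = altloc[idx], occupancy = occ[idx], aa = aa[idx],
    seq_id = seq_id[idx], icode = icode[idx]
  )

  # alternate locations: per residue keep blank altloc plus the conformer
  # with the highest mean occupancy (ties -> alphabetically first)
  pick_alt <- function(alt, occ) {
    present <- alt != " "
    if (!any(present)) return(rep(TRUE, length(alt)))
    means <- vapply(split(occ[present], alt[present]), mean, 0)
    best <- names(means)[order(-means, names(means))][1]
    !present | alt == best
  }
  at <- at[, .SD[pick_alt(altloc, occupancy)], by = res_index]

  res <- at[, .(seq_id = seq_id[1], icode = icode[1], aa = aa[1]),
            by = res_index]
  res[, `:=`(sasa = NA_real_, rasa = NA_real_, is_surface = NA)]

  structure(
    list(
      pdb_id = pdb_id, chain_id = chain,
      residues = res[, .(seq_id, icode, aa, sasa, rasa, is_surface)],
      atoms = at[, .(res_index, name, element, x, y, z, altloc, occupancy)],
      sequence = paste(res$aa, collapse = "")
    ),
    class = "antigen_structure"
  )
}

#' @export
print.antigen_structure <- function(x, ...) {
  cat(sprintf("antigen_structure %s chain %s: %d residues, %d atoms\n",
              x$pdb_id, x$chain_id, nrow(x$residues), nrow(x$atoms)))
  if (!all(is.na(x$residues$is_surface))) {
    cat(sprintf("  surface residues: %d\n", sum(x$residues$is_surface)))
  }
  invisible(x)
}

#' Number of residues in a structure
#' @param x An `antigen_structure`.
#' @export
n_residues <- function(x) nrow(x$residues)

atom_coords <- function(struct) {
  as.matrix(struct$atoms[, c("x", "y", "z")])
}

# ---- solvent accessibility ----------------------------------------------

# deterministic spiral point set on the unit sphere (golden-angle lattice)
sphere_points <- function(n) {
  i <- seq_len(n) - 0.5
  phi <- acos(1 - 2 * i / n)
  theta <- pi * (1 + sqrt(5)) * i
  cbind(sin(phi) * cos(theta), sin(phi) * sin(theta), cos(phi))
}

# canonical molecular frame: centroid-centered, principal axes with signs
# fixed by third moments, right-handed. Makes SASA exactly invariant under
# rigid rotation/translation because sampling directions co-rotate.
canonical_frame <- function(xyz) {
  ctr <- colMeans(xyz)
  xc <- sweep(xyz, 2, ctr)
  if (nrow(xc) < 3) return(xc)
  ev <- eigen(cov(xc), symmetric = TRUE)$vectors
  proj <- xc %*% ev
  for (k in 1:2) {
    m3 <- sum(proj[, k]^3)
    if (abs(m3) < 1e-8) m3 <- proj[which.max(abs(proj[, k])), k]
    if (m3 < 0) ev[, k] <- -ev[, k]
  }
  ev[, 3] <- c(ev[2, 1] * ev[3, 2] - ev[3, 1] * ev[2, 2],
               ev[3, 1] * ev[1, 2] - ev[1, 1] * ev[3, 2],
               ev[1, 1] * ev[2, 2] - ev[2, 1] * ev[1, 2])
  xc %*% ev
}

#' Compute per-residue solvent-accessible surface area
#'
#' Shrake-Rupley sphere sampling with a deterministic golden-spiral point
#' set, evaluated in a canonical molecular frame so results are invariant
#' under rigid-body motion. Populates `sasa` (square Angstrom) and `rasa`
#' (fraction of the residue type's theoretical maximum) on each residue.
#'
#' @param struct An `antigen_structure`.
#' @param probe_radius Solvent probe radius in Angstrom (default 1.4).
#' @param n_points Sample points per atom sphere (default 960).
#' @return The structure with `sasa`/`rasa` filled in.
#' @export
compute_sasa <- function(struct, probe_radius = 1.4, n_points = 960L) {
  xyz <- canonical_frame(atom_coords(struct))
  n <- nrow(xyz)
  radii <- vdw_radius(struct$atoms$element) + probe_radius
  pts <- sphere_points(n_points)

  # neighbor candidates via cell binning on the largest inflated radius
  area <- numeric(n)
  rmax <- max(radii)
  for (i in seq_len(n)) {
    d2 <- (xyz[, 1] - xyz[i, 1])^2 + (xyz[, 2] - xyz[i, 2])^2 +
      (xyz[, 3] - xyz[i, 3])^2
    nb <- which(d2 < (radii[i] + radii)^2 & seq_len(n) != i)
    if (length(nb) == 0) {
      acc <- n_points
    } else {
      sp <- pts * radii[i]
      sp <- sweep(sp, 2, xyz[i, ], `+`)
      free <- rep(TRUE, n_points)
      for (j in nb) {
        if (!any(free)) break
        dj2 <- (sp[free, 1] - xyz[j, 1])^2 + (sp[free, 2] - xyz[j, 2])^2 +
          (sp[free, 3] - xyz[j, 3])^2
        free[free] <- dj2 > radii[j]^2
      }
      acc <- sum(free)
    }
    area[i] <- 4 * pi * radii[i]^2 * acc / n_points
  }

  res_sasa <- as.numeric(rowsum(area, struct$atoms$res_index))
  struct$residues[, sasa := res_sasa]
  max_ref <- .MAX_SASA[struct$residues$aa]
  max_ref[is.na(max_ref)] <- .MAX_SASA[["G"]]
  struct$residues[, rasa := sasa / max_ref]
  struct
}

#' Total structure SASA
#' @param struct An `antigen_structure` with SASA computed.
#' @return Sum of per-residue SASA values (square Angstrom).
#' @export
structure_sasa <- function(struct) sum(struct$residues$sasa)

#' Flag surface residues by relative SASA
#'
#' @param struct An `antigen_structure` with SASA computed.
#' @param rasa_threshold Relative-SASA cutoff; residues with
#'   `rasa >= rasa_threshold` are surface (default 0.15).
#' @return The structure with `is_surface` set.
#' @export
flag_surface <- function(struct, rasa_threshold = 0.15) {
  if (all(is.na(struct$residues$sasa))) stop("compute SASA first")
  struct$residues[, is_surface := rasa >= rasa_threshold]
  struct
}

#' Indices of surface residues
#' @param struct An `antigen_structure` with surface flags.
#' @export
surface_indices <- function(struct) which(struct$residues$is_surface)

# ---- inter-residue distances --------------------------------------------

#' Minimum heavy-atom distance matrix between residues
#'
#' @param a An `antigen_structure`.
#' @param b Optional second structure; default `a` (self distances).
#' @return Matrix (residues of `a` x residues of `b`) of minimum
#'   heavy-atom pair distances in Angstrom.
#' @export
residue_distance_matrix <- function(a, b = a) {
  xa <- atom_coords(a); xb <- atom_coords(b)
  ra <- a$atoms$res_index; rb <- b$atoms$res_index
  na_r <- nrow(a$residues); nb_r <- nrow(b$residues)
  d2 <- outer(rowSums(xa^2), rowSums(xb^2), `+`) - 2 * xa %*% t(xb)
  d2[d2 < 0] <- 0
  # aggregate atom-pair distances to residue pairs by min
  cols <- matrix(Inf, nrow(xa), nb_r)
  for (j in seq_len(nb_r)) {
    jc <- which(rb == j)
    cols[, j] <- if (length(jc) == 1) d2[, jc] else
      do.call(pmin, lapply(jc, function(c) d2[, c]))
  }
  out <- matrix(Inf, na_r, nb_r)
  for (i in seq_len(na_r)) {
    ic <- which(ra == i)
    out[i, ] <- if (length(ic) == 1) cols[ic, ] else
      do.call(pmin, lapply(ic, function(r) cols[r, ]))
  }
  sqrt(out)
}

#' Minimum heavy-atom distance between two residues
#'
#' @param a Structure holding the first residue.
#' @param i Residue index in `a`.
#' @param b Structure holding the second residue (default `a`).
#' @param j Residue index in `b`.
#' @return Distance in Angstrom.
#' @export
residue_distance <- function(a, i, b = a, j) {
  xa <- atom_coords(a)[a$atoms$res_index == i, , drop = FALSE]
  xb <- atom_coords(b)[b$atoms$res_index == j, , drop = FALSE]
  if (nrow(xa) == 0 || nrow(xb) == 0) stop("residue has no atoms")
  d2 <- outer(rowSums(xa^2), rowSums(xb^2), `+`) - 2 * xa %*% t(xb)
  sqrt(max(min(d2), 0))
}

# ---- epitope labeling from complexes ------------------------------------

#' Label epitope residues from an antigen-antibody complex
#'
#' A surface residue is an epitope iff any of its heavy atoms lies within
#' `contact_cutoff` of any heavy atom of any binder chain.
#'
#' @param antigen An `antigen_structure` with surface flags.
#' @param antibody_chains List of `antigen_structure` binder chains sharing
#'   the antigen's coordinate frame.
#' @param contact_cutoff Heavy-atom contact distance in Angstrom
#'   (default 4.0, the conventional antibody-contact definition).
#' @return An `epitope_labeling`: list with `structure_key`, logical
#'   `labels` per residue, `n_positive` and `n_negative_surface`.
#' @export
label_epitopes <- function(antigen, antibody_chains, contact_cutoff = 4.0) {
  if (length(antibody_chains) == 0) stop("no binder provided")
  if (all(is.na(antigen$residues$is_surface))) stop("compute surface first")
  n <- nrow(antigen$residues)
  mind <- rep(Inf, n)
  for (ab in antibody_chains) {
    dm <- residue_distance_matrix(antigen, ab)
    mind <- pmin(mind, apply(dm, 1, min))
  }
  labels <- (mind <= contact_cutoff) & antigen$residues$is_surface
  structure(
    list(
      structure_key = c(antigen$pdb_id, antigen$chain_id),
      labels = labels,
      n_positive = sum(labels),
      n_negative_surface = sum(antigen$residues$is_surface & !labels)
    ),
    class = "epitope_labeling"
  )
}

#' @export
print.epitope_labeling <- function(x, ...) {
  cat(sprintf("epitope_labeling %s_%s: %d epitope / %d non-epitope surface\n",
              x$structure_key[1], x$structure_key[2],
              x$n_positive, x$n_negative_surface))
  invisible(x)
}

# ---- PDB output ----------------------------------------------------------

fmt_atom_line <- function(serial, name, resname, chain, seq_id, icode,
                          x, y, z, occ, b, element) {
  nm <- if (nchar(name) < 4) sprintf(" %-3s", name) else name
  sprintf("ATOM  %5d %4s %3s %s%4d%s   %8.3f%8.3f%8.3f%6.2f%6.2f          %2s",
          serial, nm, resname, chain, seq_id, icode, x, y, z, occ, b, element)
}

#' Write a structure to PDB text with scores in the B-factor column
#'
#' @param struct An `antigen_structure`.
#' @param scores Per-residue numeric scores (length = residue count); `NA`
#'   written as 0. Formatted `%6.2f` in the B-factor field.
#' @param path Optional file path; when `NULL` the text is returned.
#' @return Invisibly, the PDB lines.
#' @export
write_scored_pdb <- function(struct, scores = NULL, path = NULL) {
  res <- struct$residues
  if (is.null(scores)) scores <- rep(0, nrow(res))
  scores[is.na(scores)] <- 0
  aa1to3 <- setNames(names(.AA3), unname(.AA3))
  at <- struct$atoms
  lines <- character(nrow(at))
  for (k in seq_len(nrow(at))) {
    ri <- at$res_index[k]
    resname <- aa1to3[res$aa[ri]]
    if (is.na(resname)) resname <- "UNK"
    lines[k] <- fmt_atom_line(k, at$name[k], resname, struct$chain_id,
                              res$seq_id[ri], res$icode[ri],
                              at$x[k], at$y[k], at$z[k],
                              at$occupancy[k], scores[ri], at$element[k])
  }
  lines <- c(lines, "TER", "END")
  if (!is.null(path)) writeLines(lines, path)
  invisible(lines)
}
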