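# Seeded synthetic antigens, complexes and corpora. These are statistical
# toys, not physical proteins: residues are a jittered lattice ball with a
# single pseudo C-alpha plus 1-3 dummy side-chain atoms, a contiguous
# surface epitope cap, and N-glycosylation sequons planted with tunable
# enrichment inside the cap.

#' Specification of a synthetic antigen
#'
#' @param n_residues Residue count; must exceed 50 (the corpus filter).
#' @param epitope_patch_radius Radius (Angstrom) of the planted surface
#'   epitope cap.
#' @param n_sequons Number of planted Asn-X-Ser/Thr sequons.
#' @param sequon_epitope_enrichment Multiplier (>= 1) on the probability
#'   of planting a sequon asparagine inside the epitope cap.
#' @param composition_bias Multiplier on the sampling weight of a few
#'   subgroups (Tyr, Trp, Lys/Arg) inside the cap, giving the
#'   pattern-based features learnable signal.
#' @param noise_sd Gaussian jitter (Angstrom) on lattice positions,
#'   truncated at 1.0.
#' @param seed Integer seed fixing every random draw.
#' @return A `synth_spec` list.
#' @export
synth_spec <- function(n_residues = 80L, epitope_patch_radius = 12,
                       n_sequons = 6L, sequon_epitope_enrichment = 5,
                       composition_bias = 3, noise_sd = 0.5, seed = 1L) {
  if (n_residues <= 50) stop("n_residues must exceed 50")
  if (sequon_epitope_enrichment < 1) stop("enrichment must be >= 1")
  structure(as.list(environment()), class = "synth_spec")
}

.SPACING <- 4.5        # lattice constant (A)
.SHELL_DEPTH <- 3.0    # outer-shell depth defining patch-eligible residues
.PATCH_AA_BOOST <- c("Y", "W", "K", "R")

clip_norm <- function(v, cap) {
  nv <- sqrt(sum(v^2))
  if (nv > cap) v * cap / nv else v
}

#' Generate one synthetic antigen
#'
#' Residues sit on a jittered cubic lattice ball. A contiguous cap of
#' outer-shell residues is the planted epitope; sequence composition in
#' the cap is biased toward a few subgroups and sequon asparagines are
#' planted with the configured enrichment inside the cap. The emitted PDB
#' text round-trips through [parse_pdb()].
#'
#' @param spec A [synth_spec()].
#' @return List: `pdb_text` (single string), `structure` (parsed
#'   `antigen_structure`, SASA not yet computed), `labeling` (planted
#'   `epitope_labeling`), `sequons` (all sequon positions in the final
#'   sequence), `planted_sequons`, `patch` (epitope residue indices) and
#'   `spec`.
#' @export
generate_antigen <- function(spec) {
  stopifnot(inherits(spec, "synth_spec"))
  old <- .Random.seed_guard(spec$seed)
  on.exit(old(), add = TRUE)

  n <- spec$n_residues
  R <- .SPACING * (3 * n / (4 * pi))^(1 / 3) * 1.06
  g <- seq(-ceiling(R / .SPACING), ceiling(R / .SPACING)) * .SPACING
  grid <- as.matrix(expand.grid(x = g, y = g, z = g))
  rn <- sqrt(rowSums(grid^2))
  ord <- order(rn)
  pts <- grid[ord[seq_len(n)], , drop = FALSE]
  jit <- matrix(rnorm(3 * n, sd = spec$noise_sd), n, 3)
  jit <- t(apply(jit, 1, clip_norm, cap = 1.0))
  pts <- pts + jit

  # chain order: z-bands then azimuth, for mild sequence/space locality
  band <- round(pts[, 3] / .SPACING)
  ang <- atan2(pts[, 2], pts[, 1])
  pts <- pts[order(band, ang), , drop = FALSE]

  r_i <- sqrt(rowSums(pts^2))
  r_out <- max(r_i)
  outer_shell <- which(r_i >= r_out - .SHELL_DEPTH)

  # contiguous epitope cap around a random direction, centered on the
  # mean shell radius so the cap hugs the surface; trimmed to the actual
  # surface set after SASA so the labeling invariant (positives are
  # surface residues) holds
  u <- rnorm(3); u <- u / sqrt(sum(u^2))
  cap_center <- mean(r_i[outer_shell]) * u
  dcap <- sqrt(colSums((t(pts) - cap_center)^2))
  patch <- intersect(outer_shell,
                     which(dcap <= spec$epitope_patch_radius))
  if (length(patch) == 0) patch <- outer_shell[which.min(dcap[outer_shell])]

  # sequence: composition bias inside the cap
  aas <- unname(.AA1)
  w_out <- rep(1, 20); names(w_out) <- aas
  w_in <- w_out
  w_in[.PATCH_AA_BOOST] <- w_in[.PATCH_AA_BOOST] * spec$composition_bias
  s <- character(n)
  in_patch <- seq_len(n) %in% patch
  s[!in_patch] <- sample(aas, sum(!in_patch), replace = TRUE, prob = w_out)
  s[in_patch] <- sample(aas, sum(in_patch), replace = TRUE, prob = w_in)

  # plant sequons: weighted toward the cap, spaced >= 3 apart
  eligible <- seq_len(n - 2)
  if (spec$n_sequons * 3 > length(eligible)) {
    stop("infeasible spec: more sequons than positions")
  }
  wts <- ifelse(eligible %in% patch, spec$sequon_epitope_enrichment, 1)
  planted <- integer(0)
  pool <- eligible
  pw <- wts
  for (q in seq_len(spec$n_sequons)) {
    if (length(pool) == 0) stop("infeasible spec: more sequons than positions")
    pick <- pool[sample.int(length(pool), 1, prob = pw)]
    planted <- c(planted, pick)
    keep <- abs(pool - pick) >= 3
    pool <- pool[keep]; pw <- pw[keep]
  }
  planted <- sort(planted)
  for (i in planted) {
    s[i] <- "N"
    if (s[i + 1] == "P") s[i + 1] <- sample(setdiff(aas, "P"), 1)
    s[i + 2] <- sample(c("S", "T"), 1)
  }

  # atoms: pseudo C-alpha plus 1-3 dummy side-chain atoms biased outward
  names4 <- c("CA", "CB", "CG", "CD")
  atom_rows <- vector("list", n)
  shell_set <- seq_len(n) %in% outer_shell
  for (i in seq_len(n)) {
    # shell residues grow outward (keeps binder clearance well-defined);
    # interior residues point randomly, filling lattice cavities
    ur <- if (shell_set[i] && r_i[i] > 1e-6) pts[i, ] / r_i[i] else {
      v <- rnorm(3); v / sqrt(sum(v^2))
    }
    nside <- sample(1:3, 1)
    xyz <- matrix(0, nside + 1, 3)
    xyz[1, ] <- pts[i, ]
    for (t in seq_len(nside)) {
      tang <- clip_norm(rnorm(3, sd = 0.3), 0.6)
      xyz[t + 1, ] <- pts[i, ] + ur * (0.8 + 0.6 * t) + tang
    }
    atom_rows[[i]] <- data.table(
      res_index = i, name = names4[seq_len(nside + 1)], element = "C",
      x = xyz[, 1], y = xyz[, 2], z = xyz[, 3], altloc = " ",
      occupancy = 1.0
    )
  }
  atoms <- rbindlist(atom_rows)

  res <- data.table(seq_id = seq_len(n), icode = " ", aa = s,
                    sasa = NA_real_, rasa = NA_real_, is_surface = NA)
  struct <- structure(
    list(pdb_id = sprintf("SY%02d", spec$seed %% 100), chain_id = "A",
         residues = res, atoms = atoms, sequence = paste(s, collapse = "")),
    class = "antigen_structure"
  )
  pdb_lines <- write_scored_pdb(struct)
  pdb_text <- paste(pdb_lines, collapse = "\n")

  # solvent exposure; final epitope labels = cap members that are surface
  struct <- flag_surface(compute_sasa(struct))
  labels <- in_patch & struct$residues$is_surface
  labeling <- structure(
    list(structure_key = c(struct$pdb_id, "A"), labels = labels,
         n_positive = sum(labels),
         n_negative_surface = sum(struct$residues$is_surface & !labels)),
    class = "epitope_labeling"
  )

  list(pdb_text = pdb_text, structure = struct, labeling = labeling,
       sequons = find_sequons(s), planted_sequons = planted,
       patch = which(labels), spec = spec)
}

#' Generate a synthetic antigen-antibody complex
#'
#' Places one dummy binder atom radially above every epitope-cap residue
#' at 3.75 A from the residue's outermost atom, so [label_epitopes()]
#' recovers the planted cap exactly at the conventional 4 A cutoff; all
#' non-cap residues stay > 4.5 A from every binder atom (verified).
#'
#' @param spec A [synth_spec()], or the output of [generate_antigen()].
#' @return The antigen list plus `binder` (an `antigen_structure` chain
#'   `B`) and `complex_text` (both chains as PDB text).
#' @export
generate_complex <- function(spec) {
  ant <- if (inherits(spec, "synth_spec")) generate_antigen(spec) else spec
  st <- ant$structure
  xyz <- atom_coords(st)
  ridx <- st$atoms$res_index
  # clearance only matters for surface residues (buried ones cannot be
  # labeled epitope regardless of contact)
  nonpatch <- setdiff(which(st$residues$is_surface), ant$patch)
  np_xyz <- xyz[ridx %in% nonpatch, , drop = FALSE]
  cap_dir <- colMeans(xyz[ridx %in% ant$patch, , drop = FALSE])
  cap_dir <- cap_dir / sqrt(sum(cap_dir^2))
  min_dist <- function(p, m) {
    sqrt(min(colSums((t(m) - p)^2)))
  }
  binder_pts <- matrix(0, length(ant$patch), 3)
  for (q in seq_along(ant$patch)) {
    i <- ant$patch[q]
    rows <- which(ridx == i)
    res_xyz <- xyz[rows, , drop = FALSE]
    ctr <- colMeans(res_xyz)
    ur <- ctr / sqrt(sum(ctr^2))
    proj <- res_xyz %*% ur
    amax <- res_xyz[which.max(proj), ]
    # default direction is radial; if that grazes a non-patch residue,
    # tilt toward the cap centroid until clearance holds
    placed <- FALSE
    for (t in c(0, 0.25, 0.5, 0.75, 1, -0.25, -0.5)) {
      d <- ur + t * cap_dir
      d <- d / sqrt(sum(d^2))
      cand <- amax + 3.75 * d
      dt <- min_dist(cand, res_xyz)
      if (dt < 3.5 - 1e-9 || dt > 4.0 + 1e-9) next
      if (min_dist(cand, np_xyz) > 4.5) {
        binder_pts[q, ] <- cand
        placed <- TRUE
        break
      }
    }
    if (!placed) stop("binder clearance violated; adjust spec noise")
  }
  binder <- structure(
    list(pdb_id = st$pdb_id, chain_id = "B",
         residues = data.table(seq_id = seq_len(nrow(binder_pts)),
                               icode = " ", aa = "G", sasa = NA_real_,
                               rasa = NA_real_, is_surface = NA),
         atoms = data.table(res_index = seq_len(nrow(binder_pts)),
                            name = "CA", element = "C",
                            x = binder_pts[, 1], y = binder_pts[, 2],
                            z = binder_pts[, 3], altloc = " ",
                            occupancy = 1.0),
         sequence = paste(rep("G", nrow(binder_pts)), collapse = "")),
    class = "antigen_structure"
  )
  ab_lines <- write_scored_pdb(binder)
  ab_lines <- sub("^(ATOM  .{15})A", "\\1B", ab_lines)
  ant$binder <- binder
  ant$complex_text <- paste(c(strsplit(ant$pdb_text, "\n")[[1]],
                              ab_lines), collapse = "\n")
  ant
}

#' Generate a synthetic training corpus
#'
#' Independent antigens drawn from a spec template with per-structure
#' derived seeds, plus a deterministic manifest.
#'
#' @param n_structures Number of antigens (>= 2).
#' @param spec_template A [synth_spec()] whose seed is overridden per
#'   structure.
#' @param seed Corpus-level seed.
#' @return List with `entries` (each: `structure`, `labeling`, `sequons`,
#'   `pdb_text`, `patch`), `manifest` (data.table) and `fingerprint`.
#' @export
generate_corpus <- function(n_structures, spec_template = synth_spec(),
                            seed = 1L) {
  if (n_structures < 2) stop("corpus needs at least 2 structures")
  entries <- vector("list", n_structures)
  man <- vector("list", n_structures)
  for (i in seq_len(n_structures)) {
    sp <- spec_template
    sp$seed <- as.integer((as.numeric(seed) * 7919 + i * 104729) %%
                            2147483647)
    ant <- generate_antigen(sp)
    ant$structure$pdb_id <- sprintf("SYN%03d", i)
    ant$labeling$structure_key <- c(ant$structure$pdb_id, "A")
    entries[[i]] <- list(structure = ant$structure,
                         labeling = ant$labeling, sequons = ant$sequons,
                         pdb_text = ant$pdb_text, patch = ant$patch)
    man[[i]] <- data.table(
      id = ant$structure$pdb_id, seed = sp$seed,
      n_residues = nrow(ant$structure$residues),
      n_sequons = length(ant$sequons),
      n_epitope = ant$labeling$n_positive
    )
  }
  manifest <- rbindlist(man)
  fp <- djb2_hash(paste(capture.output(print(manifest)), collapse = "\n"))
  list(entries = entries, manifest = manifest, fingerprint = fp)
}
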