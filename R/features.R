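# Per-residue micro-environment classifiers: triangle propensity, patch
# exposure, clustering coefficient, consolidated AAindex, glycosylation
# triangle score and shell-model glycosylation AAindex.

# ---- AAindex tables ------------------------------------------------------

#' Load AAindex-style propensity tables
#'
#' Reads a TSV with one row per accession and one column per one-letter
#' amino acid. Each table is z-scored (zero mean, unit variance) over the
#' 20 residues at load; the unknown residue `"X"` maps to 0 (the mean).
#'
#' The bundled `"glyco"` set holds synthetic stand-ins for the four
#' glycosylation-related accessions (the AAindex database itself is not
#' redistributable here); the `"general"` set holds the published
#' Kyte-Doolittle hydropathy and Hopp-Woods hydrophilicity scales.
#'
#' @param which `"glyco"` or `"general"`, selecting a bundled file.
#' @param path Optional path to a replacement TSV in the same format.
#' @return Named list of named numeric vectors (accession -> residue
#'   values incl. `X = 0`).
#' @export
load_aaindex <- function(which = c("glyco", "general"), path = NULL) {
  if (is.null(path)) {
    which <- match.arg(which)
    fname <- if (which == "glyco") "aaindex_glyco_synthetic.tsv" else
      "aaindex_general.tsv"
    path <- system.file("extdata", fname, package = "epitope3d")
  }
  tab <- utils::read.table(path, header = TRUE, sep = "\t",
                           stringsAsFactors = FALSE, comment.char = "#",
                           check.names = FALSE)
  out <- lapply(seq_len(nrow(tab)), function(r) {
    v <- as.numeric(tab[r, -1])
    names(v) <- colnames(tab)[-1]
    if (length(v) != 20L || anyNA(v)) stop("AAindex row must have 20 values")
    v <- (v - mean(v)) / sd(v)
    c(v, X = 0)
  })
  names(out) <- tab[[1]]
  out
}

# ---- small feed-forward consolidator (one hidden layer, sigmoid) --------

sigmoid <- function(z) 1 / (1 + exp(-z))

#' Train a small neural-network consolidator
#'
#' One hidden layer of sigmoid units plus a sigmoid scalar output (the
#' "two-layer, ten-node" consolidator), trained full-batch with Adam on
#' weighted cross-entropy against binary labels, with early stopping on a
#' held-out validation fraction. Deterministic for a fixed seed.
#'
#' @param x Numeric matrix (rows = cases).
#' @param y Binary labels (0/1 or logical).
#' @param hidden Hidden units (default 10).
#' @param seed RNG seed for initialization and the validation split.
#' @param epochs Maximum epochs (default 300).
#' @param lr Adam learning rate (default 0.05).
#' @param val_frac Validation fraction for early stopping (default 0.15).
#' @param patience Epochs without validation improvement before stopping.
#' @param l2 L2 penalty on weights (default 1e-4).
#' @param balance Weight classes inversely to frequency (default TRUE).
#' @return An `ann_net` list with weights, input standardization and
#'   input dimension.
#' @export
ann_train <- function(x, y, hidden = 10L, seed = 1L, epochs = 300L,
                      lr = 0.05, val_frac = 0.15, patience = 30L,
                      l2 = 1e-4, balance = TRUE) {
  x <- as.matrix(x)
  y <- as.numeric(y)
  if (length(unique(y)) < 2) stop("labels are single-class")
  d <- ncol(x)
  ctr <- colMeans(x)
  scl <- apply(x, 2, sd)
  scl[scl < 1e-12] <- 1
  xs <- sweep(sweep(x, 2, ctr), 2, scl, `/`)

  w <- if (balance) {
    ifelse(y == 1, 0.5 / mean(y == 1), 0.5 / mean(y == 0))
  } else rep(1, length(y))
  w <- w / mean(w)

  old <- .Random.seed_guard(seed)
  on.exit(old(), add = TRUE)
  n <- nrow(xs)
  val <- sample.int(n, max(1L, round(val_frac * n)))
  # make sure training part keeps both classes
  if (length(unique(y[-val])) < 2) val <- val[-1]
  tr <- setdiff(seq_len(n), val)

  W1 <- matrix(rnorm(d * hidden, sd = 0.5 / sqrt(max(d, 1))), d, hidden)
  b1 <- rep(0, hidden)
  W2 <- rnorm(hidden, sd = 0.5 / sqrt(hidden))
  b2 <- 0

  pars <- list(W1 = W1, b1 = b1, W2 = W2, b2 = b2)
  m1 <- lapply(pars, function(p) p * 0)
  v1 <- lapply(pars, function(p) p * 0)
  beta1 <- 0.9; beta2 <- 0.999; eps <- 1e-8

  fwd <- function(p, xm) {
    H <- sigmoid(sweep(xm %*% p$W1, 2, p$b1, `+`))
    list(H = H, out = sigmoid(drop(H %*% p$W2) + p$b2))
  }
  loss_of <- function(p, idx) {
    o <- fwd(p, xs[idx, , drop = FALSE])$out
    o <- pmin(pmax(o, 1e-12), 1 - 1e-12)
    -mean(w[idx] * (y[idx] * log(o) + (1 - y[idx]) * log(1 - o)))
  }

  best <- pars; best_val <- Inf; wait <- 0L
  xt <- xs[tr, , drop = FALSE]; yt <- y[tr]; wt <- w[tr]
  for (t in seq_len(epochs)) {
    f <- fwd(pars, xt)
    delta <- wt * (f$out - yt) / length(yt)           # d loss / d logit
    gW2 <- drop(crossprod(f$H, delta)) + l2 * pars$W2
    gb2 <- sum(delta)
    dH <- outer(delta, pars$W2) * f$H * (1 - f$H)
    gW1 <- crossprod(xt, dH) + l2 * pars$W1
    gb1 <- colSums(dH)
    grads <- list(W1 = gW1, b1 = gb1, W2 = gW2, b2 = gb2)
    for (nm in names(pars)) {
      m1[[nm]] <- beta1 * m1[[nm]] + (1 - beta1) * grads[[nm]]
      v1[[nm]] <- beta2 * v1[[nm]] + (1 - beta2) * grads[[nm]]^2
      mhat <- m1[[nm]] / (1 - beta1^t)
      vhat <- v1[[nm]] / (1 - beta2^t)
      pars[[nm]] <- pars[[nm]] - lr * mhat / (sqrt(vhat) + eps)
    }
    vl <- loss_of(pars, val)
    if (vl < best_val - 1e-6) {
      best_val <- vl; best <- pars; wait <- 0L
    } else {
      wait <- wait + 1L
      if (wait >= patience) break
    }
  }
  strip <- function(m) { dimnames(m) <- NULL; unname(m) }
  structure(list(W1 = strip(best$W1), b1 = unname(best$b1),
                 W2 = unname(best$W2), b2 = unname(best$b2),
                 center = unname(ctr), scale = unname(scl), dim = d),
            class = "ann_net")
}

#' Evaluate a trained consolidator
#'
#' @param net An `ann_net` from [ann_train()].
#' @param x Numeric matrix (or vector for a single case) whose column
#'   count must equal the training dimension.
#' @return Numeric vector of outputs in (0, 1).
#' @export
ann_predict <- function(net, x) {
  if (is.null(dim(x))) x <- matrix(x, nrow = 1)
  x <- as.matrix(x)
  if (ncol(x) != net$dim) stop("pattern dimension mismatch")
  xs <- sweep(sweep(x, 2, net$center), 2, net$scale, `/`)
  H <- sigmoid(sweep(xs %*% net$W1, 2, net$b1, `+`))
  sigmoid(drop(H %*% net$W2) + net$b2)
}

# seed RNG locally, restoring caller state
.Random.seed_guard <- function(seed) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  set.seed(seed)
  function() {
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  }
}

# ---- geometry cache ------------------------------------------------------

#' Precompute label-independent per-structure geometry
#'
#' Everything the six classifiers need that does not depend on training
#' labels: distance matrix, surface triangles (with glytri flags), the
#' contact graph, clustering coefficients, patch exposure, consolidated
#' general AAindex, shell profiles, per-residue triangle pattern counts
#' and calibration neighbor lists. Computing this once per structure lets
#' cross-validation retrain models cheaply.
#'
#' @param struct An `antigen_structure` with SASA and surface flags.
#' @param config Pipeline configuration, see [ep3_config()].
#' @param subgroups Subgroup map.
#' @param aaindex_general,aaindex_glyco AAindex table lists.
#' @return A `structure_geometry` list.
#' @export
structure_geometry <- function(struct, config = ep3_config(),
                               subgroups = load_subgroup_table(),
                               aaindex_general = load_aaindex("general"),
                               aaindex_glyco = load_aaindex("glyco")) {
  dmat <- residue_distance_matrix(struct)
  surf <- which(struct$residues$is_surface)
  sequons <- find_sequons(struct$sequence)
  tri <- enumerate_triangles(struct, max_dist = config$triangle_dist,
                             dmat = dmat, subgroups = subgroups)
  tri <- mark_glyco(tri, sequons)

  n <- nrow(struct$residues)
  aa <- struct$residues$aa

  # triangle membership per surface residue
  tri_by_res <- vector("list", n)
  if (nrow(tri)) {
    long <- data.table(res = c(tri$i, tri$j, tri$k),
                       row = rep(seq_len(nrow(tri)), 3L))
    sp <- split(long$row, long$res)
    tri_by_res[as.integer(names(sp))] <- sp
  }

  # contact graph over surface residues
  A <- dmat[surf, surf, drop = FALSE] <= config$contact_dist
  diag(A) <- FALSE
  cc <- numeric(n)
  idxv <- numeric(n)
  genmat <- vapply(aaindex_general, function(v) v[aa], numeric(n))
  for (s in seq_along(surf)) {
    r <- surf[s]
    nb <- which(A[s, ])
    k <- length(nb)
    cc[r] <- if (k < 2) 0 else {
      sub <- A[nb, nb, drop = FALSE]
      sum(sub) / (k * (k - 1))
    }
    hood <- c(r, surf[nb])
    idxv[r] <- mean(colMeans(genmat[hood, , drop = FALSE]))
  }

  # patch exposure: mean rasa over the union of the residue's triangles
  apref <- numeric(n)
  rasa <- struct$residues$rasa
  for (r in surf) {
    rows <- tri_by_res[[r]]
    mem <- if (is.null(rows)) r else
      unique(c(r, tri$i[rows], tri$j[rows], tri$k[rows]))
    apref[r] <- mean(rasa[mem])
  }

  # shell profiles (all residues as neighbors, center excluded)
  nlayers <- as.integer(round(config$shell_radius / config$shell_step))
  K <- length(aaindex_glyco)
  glymat <- vapply(aaindex_glyco, function(v) v[aa], numeric(n))
  shells <- matrix(0, n, nlayers * K)
  shell_counts <- matrix(0L, n, nlayers)
  # column order: accession-major blocks, layers 1..nlayers within each
  colnames(shells) <- as.vector(vapply(names(aaindex_glyco), function(acc) {
    paste0(acc, "_L", seq_len(nlayers))
  }, character(nlayers)))
  for (r in surf) {
    d <- dmat[r, ]
    d[r] <- Inf
    lay <- floor(d / config$shell_step) + 1L
    ok <- which(d < config$shell_radius)
    if (length(ok) == 0) next
    for (j in unique(lay[ok])) {
      mem <- ok[lay[ok] == j]
      shell_counts[r, j] <- length(mem)
      for (ki in seq_len(K)) {
        shells[r, (ki - 1L) * nlayers + j] <-
          mean(glymat[mem, ki])
      }
    }
  }

  # per-residue triangle pattern counts (for propensity + glytri weights)
  pat_counts <- NULL
  gly_counts <- NULL
  if (nrow(tri)) {
    long <- rbindlist(list(
      tri[, .(res = i, pattern, has_x, is_glytri)],
      tri[, .(res = j, pattern, has_x, is_glytri)],
      tri[, .(res = k, pattern, has_x, is_glytri)]
    ))
    pat_counts <- long[has_x == FALSE, .(count = .N), by = .(res, pattern)]
    gly_counts <- long[has_x == FALSE & is_glytri == TRUE,
                       .(count = .N), by = .(res, pattern)]
  } else {
    pat_counts <- data.table(res = integer(0), pattern = character(0),
                             count = integer(0))
    gly_counts <- copy(pat_counts)
  }

  # calibration neighborhoods (surface residues within calib_dist, self incl.)
  nb5 <- vector("list", n)
  for (r in surf) nb5[[r]] <- surf[dmat[r, surf] <= config$calib_dist]

  # triangle totals per residue incl. X triangles (count features)
  n_tri <- vapply(tri_by_res, function(v) if (is.null(v)) 0L else length(v),
                  integer(1))

  structure(
    list(dmat = dmat, surf = surf, sequons = sequons, triangles = tri,
         tri_by_res = tri_by_res, n_tri = n_tri, cc = cc, apref = apref,
         index = idxv, shells = shells, shell_counts = shell_counts,
         pat_counts = pat_counts, gly_counts = gly_counts, nb5 = nb5,
         config = config),
    class = "structure_geometry"
  )
}

# ---- individual classifiers (thin wrappers over the geometry cache) -----

#' Triangle propensity index of a residue
#'
#' Mean, over all unit triangles containing the residue, of the corpus
#' log-odds score of the triangle's subgroup pattern
#' (`log((f_epi + eps) / (f_surf + eps))`). Unseen and unknown-residue
#' patterns score 0; a residue with no triangles scores 0.
#'
#' @param geom A `structure_geometry`.
#' @param center Residue index.
#' @param prop_table A `propensity_table` from [propensity_table()].
#' @return Scalar propensity value.
#' @export
propensity_avg <- function(geom, center, prop_table) {
  if (is.null(prop_table)) stop("propensity table not trained")
  rows <- geom$tri_by_res[[center]]
  if (is.null(rows) || length(rows) == 0) return(0)
  tr <- geom$triangles[rows]
  lo <- prop_table$logodds[match(tr$pattern, prop_table$pattern)]
  lo[is.na(lo)] <- 0
  lo[tr$has_x] <- 0
  mean(lo)
}

#' Relative ASA preference (patch exposure) of a residue
#'
#' Mean relative SASA over the union of residues in the residue's unit
#' triangles, itself included; its own rASA when it has no triangles.
#'
#' @param geom A `structure_geometry`.
#' @param center Residue index.
#' @return Scalar in `[0, ~1]`.
#' @export
relative_asa_pref <- function(geom, center) geom$apref[center]

#' Local clustering coefficient on the surface contact graph
#'
#' Fraction of realized edges among the neighbors of the residue in the
#' surface contact graph (edge iff minimum heavy-atom distance is at most
#' the contact distance); 0 for degree < 2.
#'
#' @param geom A `structure_geometry`.
#' @param center Residue index.
#' @return Scalar in `[0, 1]`.
#' @export
clustering_coeff <- function(geom, center) geom$cc[center]

#' Consolidated general AAindex of a residue neighborhood
#'
#' Mean over the general AAindex tables of the mean (z-scored) index value
#' of the residue and its surface contact neighbors.
#'
#' @param geom A `structure_geometry`.
#' @param center Residue index.
#' @return Scalar value.
#' @export
consolidated_aaindex <- function(geom, center) geom$index[center]

#' Glycosylation-triangle pattern weights of a residue
#'
#' For each ratio-table pattern `i`, `W_ri = ratio_i * N_occur(i)` where
#' `N_occur(i)` counts glycosylation triangles of pattern `i` containing
#' the residue within the triangle radius.
#'
#' @param geom A `structure_geometry`.
#' @param center Residue index.
#' @param ratio_table A `pattern_ratio_table`.
#' @return Named numeric vector over the table's patterns (dense; zero for
#'   patterns not occurring at this residue).
#' @export
glytri_weights <- function(geom, center, ratio_table) {
  if (is.null(ratio_table)) stop("ratio table not trained")
  w <- setNames(numeric(nrow(ratio_table)), ratio_table$pattern)
  gc <- geom$gly_counts[res == center]
  if (nrow(gc)) {
    m <- match(gc$pattern, ratio_table$pattern)
    keep <- !is.na(m)
    w[m[keep]] <- ratio_table$ratio[m[keep]] * gc$count[keep]
  }
  w
}

#' Shell-model AAindex profile of a residue
#'
#' Neighboring residues (center excluded) are binned by minimum heavy-atom
#' distance into half-open layers `[0,2), [2,4), ..., [8,10)` Angstrom;
#' per layer and per glycosylation AAindex table, the mean (z-scored)
#' index value of binned residues. Empty layers record mean 0, count 0.
#'
#' @param geom A `structure_geometry`.
#' @param center Residue index.
#' @return List with `layer_means` (layers x tables matrix) and
#'   `layer_counts`.
#' @export
shell_profile <- function(geom, center) {
  nlayers <- as.integer(round(geom$config$shell_radius /
                                geom$config$shell_step))
  K <- ncol(geom$shells) / nlayers
  lm <- matrix(geom$shells[center, ], nrow = nlayers)
  colnames(lm) <- unique(sub("_L[0-9]+$", "", colnames(geom$shells)))
  list(layer_means = lm, layer_counts = geom$shell_counts[center, ])
}

#' Consolidated glycosylation-triangle score
#'
#' @param weights Named weight vector from [glytri_weights()] (names must
#'   match the consolidator's training vocabulary).
#' @param net Trained `ann_net`.
#' @param vocab Pattern vocabulary the net was trained on.
#' @return Scalar in (0, 1).
#' @export
consolidate_glytri <- function(weights, net, vocab) {
  if (length(weights) != length(vocab) ||
      !all(names(weights) == vocab)) stop("pattern dimension mismatch")
  ann_predict(net, matrix(weights, nrow = 1))
}

#' Consolidated glycosylation AAindex
#'
#' @param shell_values Named vector of the 20 candidate shell features
#'   (`<accession>_L<layer>`).
#' @param selection Character vector of selected candidate names.
#' @param net Trained `ann_net` over the selection.
#' @return Scalar in (0, 1).
#' @export
consolidate_glyindex <- function(shell_values, selection, net) {
  if (!all(selection %in% names(shell_values))) {
    stop("selection/consolidator dimension mismatch")
  }
  if (net$dim != length(selection)) {
    stop("selection/consolidator dimension mismatch")
  }
  ann_predict(net, matrix(shell_values[selection], nrow = 1))
}

# ---- full featurization --------------------------------------------------

# dense per-residue glytri weight matrix over a pattern vocabulary
glytri_weight_matrix <- function(geom, ratio_table) {
  n <- length(geom$n_tri)
  W <- matrix(0, n, nrow(ratio_table),
              dimnames = list(NULL, ratio_table$pattern))
  gc <- geom$gly_counts
  if (nrow(gc)) {
    m <- match(gc$pattern, ratio_table$pattern)
    keep <- !is.na(m)
    W[cbind(gc$res[keep], m[keep])] <- ratio_table$ratio[m[keep]] *
      gc$count[keep]
  }
  W
}

# per-residue propensity values from the cached pattern counts
propensity_vector <- function(geom, prop_table) {
  n <- length(geom$n_tri)
  avg <- numeric(n)
  pc <- geom$pat_counts
  if (nrow(pc)) {
    pc <- copy(pc)
    pc[, lo := {
      v <- prop_table$logodds[match(pattern, prop_table$pattern)]
      v[is.na(v)] <- 0
      v
    }]
    sums <- pc[, .(s = sum(count * lo)), by = res]
    # sum over non-X triangles; denominator counts all triangles
    avg[sums$res] <- sums$s
  }
  tot <- geom$n_tri
  ok <- tot > 0
  avg[ok] <- avg[ok] / tot[ok]
  avg
}

#' Compute the six classifier values for every surface residue
#'
#' @param struct An `antigen_structure` with SASA and surface flags.
#' @param model A trained `epitope_model`.
#' @param geom Optional precomputed [structure_geometry()].
#' @return data.table with `res_index`, `aa` and the six feature columns
#'   `avg`, `apref`, `cc`, `index`, `glytri`, `glyindex`.
#' @export
featurize <- function(struct, model, geom = NULL) {
  if (is.null(geom)) {
    geom <- structure_geometry(struct, model$config,
                               subgroups = model$subgroups,
                               aaindex_general = model$aaindex_general,
                               aaindex_glyco = model$aaindex_glyco)
  }
  surf <- geom$surf
  avg <- propensity_vector(geom, model$propensity_table)
  gly <- if (is.null(model$glytri_net)) rep(0, length(surf)) else {
    W <- glytri_weight_matrix(geom, model$ratio_table)
    ann_predict(model$glytri_net, W[surf, , drop = FALSE])
  }
  gidx <- if (is.null(model$glyindex_net)) rep(0, length(surf)) else {
    sh <- geom$shells[surf, model$glyindex_selection, drop = FALSE]
    ann_predict(model$glyindex_net, sh)
  }
  data.table(
    res_index = surf,
    aa = struct$residues$aa[surf],
    avg = avg[surf],
    apref = geom$apref[surf],
    cc = geom$cc[surf],
    index = geom$index[surf],
    glytri = as.numeric(gly),
    glyindex = as.numeric(gidx)
  )
}

# ---- propensity table (corpus log-odds of triangle patterns) ------------

#' Train the triangle-pattern propensity table
#'
#' Corpus frequencies of each subgroup pattern among epitope triangles
#' (at least two epitope members) and among all surface triangles, turned
#' into a log-odds score `log((f_epi + eps) / (f_surf + eps))`.
#'
#' @param corpus List of entries with `structure`, `labeling` and
#'   optionally `geometry`.
#' @param epsilon Pseudo-frequency guarding `log(0)` (default 1e-6).
#' @param max_dist Triangle edge cutoff.
#' @param subgroups Subgroup map.
#' @return A `propensity_table` data.table (`pattern`, `f_epi`, `f_surf`,
#'   `logodds`).
#' @export
propensity_table <- function(corpus, epsilon = 1e-6, max_dist = 15,
                             subgroups = load_subgroup_table()) {
  pieces <- lapply(corpus, function(entry) {
    tr <- if (!is.null(entry$geometry)) entry$geometry$triangles else
      enumerate_triangles(entry$structure, max_dist = max_dist,
                          subgroups = subgroups)
    lab <- entry$labeling$labels
    tr <- tr[has_x == FALSE]
    if (nrow(tr) == 0) return(NULL)
    tr[, epi := (as.integer(lab[i]) + as.integer(lab[j]) +
                   as.integer(lab[k])) >= 2L]
    tr[, .(n_epi = sum(epi), n_all = .N), by = pattern]
  })
  allc <- rbindlist(pieces[!vapply(pieces, is.null, TRUE)])
  if (nrow(allc) == 0) stop("no surface triangles in corpus")
  tab <- allc[, .(n_epi = sum(n_epi), n_all = sum(n_all)), by = pattern]
  tot_epi <- sum(tab$n_epi); tot_all <- sum(tab$n_all)
  tab[, f_epi := if (tot_epi > 0) n_epi / tot_epi else 0]
  tab[, f_surf := n_all / tot_all]
  tab[, logodds := log((f_epi + epsilon) / (f_surf + epsilon))]
  setkey(tab, pattern)
  setattr(tab, "class", c("propensity_table", class(tab)))
  tab[]
}
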