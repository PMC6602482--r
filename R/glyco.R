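# N-glycosylation sequons, surface residue triangles, glycosylation
# triangles and their epitope-enrichment ratio table.

#' Find N-glycosylation sequons in a sequence
#'
#' A sequon is Asn-X-Ser/Thr where X is any residue except proline. An
#' unknown residue (`"X"`) is allowed in the middle slot (it could be
#' anything but we cannot prove it is proline) but does not match the
#' Ser/Thr slot. Overlapping sequons are all reported.
#'
#' @param sequence One-letter amino-acid string (or character vector of
#'   single letters).
#' @return Sorted integer vector of 1-based positions of sequon
#'   asparagines (possibly empty).
#' @export
find_sequons <- function(sequence) {
  s <- if (length(sequence) == 1L) strsplit(sequence, "")[[1]] else sequence
  n <- length(s)
  if (n < 3) return(integer(0))
  i <- seq_len(n - 2)
  which(s[i] == "N" & s[i + 1] != "P" & s[i + 2] %in% c("S", "T"))
}

# ---- functional subgroups ------------------------------------------------

#' Load the amino-acid functional-subgroup table
#'
#' Thirteen functional subgroups over the 20 standard residues, plus a
#' reserved 14th catch-all group for `"X"`. The bundled default groups
#' residues by side-chain chemistry; an alternative grouping in the same
#' two-column TSV format (`aa`, `group`) can be supplied.
#'
#' @param path Optional path to a TSV replacing the bundled table.
#' @return Named character vector: one-letter amino acid -> subgroup id.
#' @export
load_subgroup_table <- function(path = NULL) {
  if (is.null(path)) {
    path <- system.file("extdata", "subgroups.tsv", package = "epitope3d")
  }
  tab <- utils::read.table(path, header = TRUE, sep = "\t",
                           stringsAsFactors = FALSE, comment.char = "#")
  map <- setNames(tab$group, tab$aa)
  if (length(unique(map)) != 13L) stop("subgroup table must define 13 groups")
  if (!all(unname(.AA1) %in% names(map))) {
    stop("subgroup table must cover all 20 standard residues")
  }
  c(map, X = "G14")
}

#' Canonical pattern key of a residue triple
#'
#' @param aas Character vector of three one-letter amino acids.
#' @param subgroups Subgroup map from [load_subgroup_table()].
#' @return Pattern key: the sorted subgroup ids joined by `"-"`.
#' @export
triangle_pattern <- function(aas, subgroups) {
  paste(sort(subgroups[aas]), collapse = "-")
}

# ---- triangle enumeration ------------------------------------------------

#' Enumerate surface residue triangles
#'
#' A unit triangle is an unordered triple of surface residues whose three
#' pairwise minimum heavy-atom distances are all `<= max_dist`.
#'
#' @param struct An `antigen_structure` with surface flags.
#' @param center Optional residue index; when given, only triangles
#'   containing it are returned (empty if it is not a surface residue).
#' @param max_dist Edge cutoff in Angstrom (default 15).
#' @param dmat Optional precomputed [residue_distance_matrix()].
#' @param subgroups Subgroup map (default bundled table).
#' @return data.table with columns `i < j < k` (residue indices),
#'   `pattern` (canonical subgroup key) and `has_x` (any member unknown).
#' @export
enumerate_triangles <- function(struct, center = NULL, max_dist = 15,
                                dmat = NULL,
                                subgroups = load_subgroup_table()) {
  if (all(is.na(struct$residues$is_surface))) stop("compute surface first")
  if (is.null(dmat)) dmat <- residue_distance_matrix(struct)
  surf <- which(struct$residues$is_surface)
  empty <- data.table(i = integer(0), j = integer(0), k = integer(0),
                      pattern = character(0), has_x = logical(0))
  if (!is.null(center) && !(center %in% surf)) return(empty)
  m <- length(surf)
  if (m < 3) return(empty)

  A <- dmat[surf, surf, drop = FALSE] <= max_dist
  diag(A) <- FALSE
  tri <- vector("list", m)
  for (a in seq_len(m - 2)) {
    nb <- which(A[a, ] & seq_len(m) > a)
    if (length(nb) < 2) next
    rows <- list()
    for (b in nb[nb <= m - 1]) {
      ck <- nb[nb > b & A[b, nb]]
      if (length(ck)) rows[[length(rows) + 1L]] <- cbind(a, b, ck)
    }
    if (length(rows)) tri[[a]] <- do.call(rbind, rows)
  }
  tri <- tri[!vapply(tri, is.null, TRUE)]
  if (length(tri) == 0) return(empty)
  tm <- do.call(rbind, tri)
  out <- data.table(i = surf[tm[, 1]], j = surf[tm[, 2]], k = surf[tm[, 3]])
  if (!is.null(center)) {
    out <- out[i == center | j == center | k == center]
    if (nrow(out) == 0) return(empty)
  }
  aa <- struct$residues$aa
  g1 <- subgroups[aa[out$i]]; g2 <- subgroups[aa[out$j]]
  g3 <- subgroups[aa[out$k]]
  keys <- matrix(c(g1, g2, g3), ncol = 3)
  out[, pattern := apply(keys, 1, function(g) paste(sort(g), collapse = "-"))]
  out[, has_x := aa[i] == "X" | aa[j] == "X" | aa[k] == "X"]
  out[]
}

#' Mark glycosylation triangles
#'
#' A glycosylation triangle (glytri) is a surface triangle with at least
#' one member that is the asparagine of an N-glycosylation sequon. With
#' training labels, an epitope glycosylation triangle (epi_glytri) is a
#' glytri containing at least two epitope residues.
#'
#' @param triangles Output of [enumerate_triangles()].
#' @param sequons Positions from [find_sequons()] on the same structure.
#' @param labels Optional `epitope_labeling` for epi_glytri flags.
#' @return The triangle table with `is_glytri` and `is_epi_glytri` columns
#'   (`is_epi_glytri` is `NA` without labels).
#' @export
mark_glyco <- function(triangles, sequons, labels = NULL) {
  tr <- copy(triangles)
  tr[, is_glytri := i %in% sequons | j %in% sequons | k %in% sequons]
  if (is.null(labels)) {
    tr[, is_epi_glytri := NA]
  } else {
    lab <- labels$labels
    tr[, is_epi_glytri := is_glytri &
         (as.integer(lab[i]) + as.integer(lab[j]) + as.integer(lab[k])) >= 2L]
  }
  tr[]
}

# ---- ratio table (epitope enrichment of glytri patterns) ----------------

#' Estimate the glycosylation-triangle pattern ratio table
#'
#' For every glytri subgroup pattern observed in a labeled training corpus,
#' the ratio of epitope glycosylation triangles to all glycosylation
#' triangles of that pattern: `ratio_i = N_epi_glytri_i / N_glytri_i`.
#' Each unique triangle is counted once per structure. Triangles with an
#' unknown (`"X"`) member are excluded from pattern statistics. Patterns
#' never observed are absent from the table and score 0 downstream.
#'
#' @param corpus List of entries, each a list with `structure` (surface
#'   flags computed), `labeling` (`epitope_labeling`) and optionally
#'   `sequons` (recomputed from the sequence when missing) and `geometry`.
#' @param max_dist Triangle edge cutoff (default 15).
#' @param subgroups Subgroup map.
#' @return A `pattern_ratio_table`: data.table (`pattern`, `n_epi_glytri`,
#'   `n_glytri`, `ratio`) with attribute `n_patterns`.
#' @export
compute_ratio_table <- function(corpus, max_dist = 15,
                                subgroups = load_subgroup_table()) {
  pieces <- lapply(corpus, function(entry) {
    st <- entry$structure
    seqn <- entry$sequons
    if (is.null(seqn)) seqn <- find_sequons(st$sequence)
    tr <- if (!is.null(entry$geometry)) entry$geometry$triangles else
      enumerate_triangles(st, max_dist = max_dist, subgroups = subgroups)
    tr <- mark_glyco(tr, seqn, entry$labeling)
    tr[is_glytri == TRUE & has_x == FALSE,
       .(n_epi_glytri = sum(is_epi_glytri), n_glytri = .N), by = pattern]
  })
  allc <- rbindlist(pieces)
  if (nrow(allc) == 0) stop("no glycosylation triangles in corpus")
  tab <- allc[, .(n_epi_glytri = sum(n_epi_glytri),
                  n_glytri = sum(n_glytri)), by = pattern]
  tab[, ratio := n_epi_glytri / n_glytri]
  setkey(tab, pattern)
  setattr(tab, "n_patterns", nrow(tab))
  setattr(tab, "class", c("pattern_ratio_table", class(tab)))
  tab[]
}

#' Serialize a ratio table to JSON
#'
#' @param table A `pattern_ratio_table`.
#' @param path Output path.
#' @export
write_ratio_table <- function(table, path) {
  obj <- list(
    schema = "epitope3d/pattern_ratio_table",
    version = 1L,
    n_patterns = nrow(table),
    entries = lapply(seq_len(nrow(table)), function(r) {
      list(pattern = table$pattern[r],
           n_epi_glytri = table$n_epi_glytri[r],
           n_glytri = table$n_glytri[r],
           ratio = table$ratio[r])
    })
  )
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Read a ratio table from JSON
#' @param path Path written by [write_ratio_table()].
#' @return A `pattern_ratio_table`.
#' @export
read_ratio_table <- function(path) {
  obj <- jsonlite::read_json(path)
  if (!identical(obj$schema, "epitope3d/pattern_ratio_table")) {
    stop("not a ratio table file")
  }
  tab <- rbindlist(lapply(obj$entries, function(e) {
    data.table(pattern = e$pattern,
               n_epi_glytri = as.integer(e$n_epi_glytri),
               n_glytri = as.integer(e$n_glytri), ratio = as.numeric(e$ratio))
  }))
  setkey(tab, pattern)
  setattr(tab, "n_patterns", nrow(tab))
  setattr(tab, "class", c("pattern_ratio_table", class(tab)))
  tab[]
}
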