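#' Length-scaled geometry score
#'
#' Container for a GOAP-style statistical-potential score where more
#' negative means better geometry and comparability across proteins is
#' achieved by dividing the raw total by the sequence length.
#'
#' @param raw_total raw score total (more negative = better).
#' @param n_residues number of residues used for scaling (>= 1).
#' @param source `"external_goap"` (adapter-read table) or
#'   `"internal_fallback"` (built-in stereochemistry score).
#' @return object of class `geometry_score` with fields `raw_total`,
#'   `scaled`, `n_residues`, `source`.
#' @export
geometry_score <- function(raw_total, n_residues,
                           source = c("external_goap", "internal_fallback")) {
  source <- match.arg(source)
  structure(list(raw_total = raw_total,
                 scaled = scaled_score(raw_total, n_residues),
                 n_residues = as.integer(n_residues), source = source),
            class = "geometry_score")
}

#' Scale a raw geometry score by sequence length
#' @param raw_total raw score total.
#' @param n_residues sequence length (>= 1).
#' @return `raw_total / n_residues`.
#' @export
scaled_score <- function(raw_total, n_residues) {
  if (length(n_residues) != 1 || n_residues < 1)
    stop("n_residues must be a positive integer")
  raw_total / n_residues
}

#' Geometry-filter configuration
#'
#' Models whose scaled score is strictly above the threshold are
#' discarded; a score exactly at the threshold is kept. The default of
#' -100 is a round, admittedly arbitrary cutoff that separates
#' well-folded models from misfolded ones for GOAP-scaled scores.
#'
#' @param threshold scaled-score cutoff (default -100).
#' @return object of class `filter_config`.
#' @export
filter_config <- function(threshold = -100) {
  structure(list(threshold = threshold), class = "filter_config")
}

#' Read an external geometry-score table and align it to an ensemble
#'
#' Adapter for tables produced by an external scoring program (e.g. GOAP).
#' The table is CSV with at least columns `model_label` and `raw_total`;
#' rows are matched to ensemble order by label when the ensemble carries
#' source labels, otherwise by row order.
#'
#' @param path CSV path.
#' @param ens an `ensemble`.
#' @return list of `geometry_score`, one per model, in ensemble order.
#' @export
read_external_scores <- function(path, ens) {
  tab <- utils::read.csv(path, stringsAsFactors = FALSE)
  if (!all(c("model_label", "raw_total") %in% names(tab)))
    stop("score table needs columns model_label, raw_total")
  if (nrow(tab) != length(ens))
    stop("alignment error: ", nrow(tab), " score rows for ",
         length(ens), " models")
  if (!is.null(ens$source_labels)) {
    idx <- match(ens$source_labels, tab$model_label)
    if (any(is.na(idx)))
      stop("alignment error: missing labels ",
           paste(utils::head(ens$source_labels[is.na(idx)], 5),
                 collapse = ", "))
    tab <- tab[idx, , drop = FALSE]
  }
  lapply(seq_len(nrow(tab)), function(i) {
    geometry_score(tab$raw_total[i], n_residues(ens$models[[i]]),
                   source = "external_goap")
  })
}

#' Write a geometry-score table as CSV
#' @param scores list of `geometry_score`.
#' @param path output CSV path.
#' @param labels optional model labels (default model_1, ...).
#' @export
write_scores <- function(scores, path, labels = NULL) {
  if (is.null(labels)) labels <- sprintf("model_%d", seq_along(scores))
  utils::write.csv(data.frame(
    model_label = labels,
    raw_total = vapply(scores, `[[`, 0, "raw_total"),
    n_residues = vapply(scores, `[[`, 0L, "n_residues"),
    scaled = vapply(scores, `[[`, 0, "scaled"),
    source = vapply(scores, `[[`, "", "source")), path,
    row.names = FALSE)
  invisible(path)
}

VDW_RADII <- c(C = 1.70, N = 1.55, O = 1.52, S = 1.80, P = 1.80,
               SE = 1.90, F = 1.47, CL = 1.75, BR = 1.85)

# atom pairs within bonded-graph distance <= max_sep, from a topological
# bond list (indices into the full atom table)
bonded_exclusions <- function(n_atoms, bonds, max_sep = 3) {
  adj <- vector("list", n_atoms)
  for (b in seq_len(nrow(bonds))) {
    adj[[bonds$i[b]]] <- c(adj[[bonds$i[b]]], bonds$j[b])
    adj[[bonds$j[b]]] <- c(adj[[bonds$j[b]]], bonds$i[b])
  }
  out_i <- integer(0); out_j <- integer(0)
  for (s in seq_len(n_atoms)) {
    reach <- s
    frontier <- s
    for (dep in seq_len(max_sep)) {
      frontier <- setdiff(unique(unlist(adj[frontier])), reach)
      if (!length(frontier)) break
      reach <- c(reach, frontier)
    }
    reach <- reach[reach > s]
    out_i <- c(out_i, rep(s, length(reach)))
    out_j <- c(out_j, reach)
  }
  cbind(out_i, out_j)
}

#' Heavy-atom clash score (clashes per 1000 atoms)
#'
#' A simplified MolProbity-style steric metric: counts unordered
#' non-bonded heavy-atom pairs whose distance is below the sum of their
#' van der Waals radii minus `overlap_cutoff`. Pairs within one residue
#' and pairs within bonded-graph distance 3 (1-2, 1-3 and 1-4
#' neighbours, from standard residue connectivity including the peptide
#' bond) are excluded; hydrogens are ignored. This approximates, but does
#' not reproduce, a full MolProbity clashscore (no hydrogen placement, no
#' rotamer analysis).
#'
#' @param model a `structure_model`.
#' @param overlap_cutoff allowed overlap before a pair counts as a clash,
#'   Angstrom (default 0.4).
#' @param radii named numeric vector of van der Waals radii (Angstrom)
#'   overriding or extending the built-in element table.
#' @return clashes per 1000 heavy atoms.
#' @export
clash_score <- function(model, overlap_cutoff = 0.4, radii = NULL) {
  heavy <- which(heavy_mask(model))
  a <- model$atoms[heavy, , drop = FALSE]
  n <- nrow(a)
  if (n < 2) stop("need >= 2 heavy atoms")
  el <- toupper(a$element)
  tab <- VDW_RADII
  if (!is.null(radii)) tab[toupper(names(radii))] <- radii
  r <- tab[el]
  if (anyNA(r)) {
    warning("unknown element(s) ", paste(unique(el[is.na(r)]), collapse = ","),
            ": using default vdW radius 1.7 A")
    r[is.na(r)] <- 1.7
  }
  xyz <- as.matrix(a[, c("x", "y", "z")])
  d <- as.matrix(stats::dist(xyz))
  thr <- outer(r, r, "+") - overlap_cutoff
  clash <- d < thr
  reskey <- paste(a$chain, a$resno, a$insert, sep = "\r")
  clash[outer(reskey, reskey, "==")] <- FALSE
  named <- backbone_bonds(model)  # topological, coordinate-independent
  remap <- match(seq_len(nrow(model$atoms)), heavy)
  keep <- !is.na(remap[named$i]) & !is.na(remap[named$j])
  bonds <- data.frame(i = remap[named$i[keep]], j = remap[named$j[keep]])
  if (nrow(bonds)) {
    ex <- bonded_exclusions(n, bonds, max_sep = 3)
    if (nrow(ex)) {
      clash[ex] <- FALSE
      clash[ex[, c(2, 1), drop = FALSE]] <- FALSE
    }
  }
  diag(clash) <- FALSE
  1000 * sum(clash[upper.tri(clash)]) / n
}

IDEAL_BOND_LENGTHS <- c("N-CA" = 1.458, "CA-C" = 1.525, "C-O" = 1.231,
                        "CA-CB" = 1.521, "C-N" = 1.329)

# backbone bond list (atom row indices + ideal length) for protein residues
backbone_bonds <- function(model) {
  a <- model$atoms
  prot <- which(!a$het)
  key <- paste(a$chain, a$resno, a$insert, sep = "\r")
  find <- function(res_key, nm) {
    i <- prot[key[prot] == res_key & a$name[prot] == nm]
    if (length(i)) i[1] else NA_integer_
  }
  rt <- residue_table(model)
  rkey <- paste(rt$chain, rt$resno, rt$insert, sep = "\r")
  ii <- integer(0); jj <- integer(0); ideal <- numeric(0)
  add <- function(i, j, d0) {
    if (!is.na(i) && !is.na(j)) {
      ii <<- c(ii, i); jj <<- c(jj, j); ideal <<- c(ideal, d0)
    }
  }
  for (r in seq_len(nrow(rt))) {
    add(find(rkey[r], "N"), find(rkey[r], "CA"), IDEAL_BOND_LENGTHS["N-CA"])
    add(find(rkey[r], "CA"), find(rkey[r], "C"), IDEAL_BOND_LENGTHS["CA-C"])
    add(find(rkey[r], "C"), find(rkey[r], "O"), IDEAL_BOND_LENGTHS["C-O"])
    add(find(rkey[r], "CA"), find(rkey[r], "CB"),
        IDEAL_BOND_LENGTHS["CA-CB"])
    if (r < nrow(rt) && rt$chain[r + 1] == rt$chain[r])
      add(find(rkey[r], "C"), find(rkey[r + 1], "N"),
          IDEAL_BOND_LENGTHS["C-N"])
  }
  data.frame(i = ii, j = jj, ideal = ideal)
}

#' Internal fallback geometry score
#'
#' A stereochemistry-based stand-in for an external statistical potential,
#' so the filtering stage runs without any third-party scoring program:
#' `scaled = -(base - w_clash * clashscore - w_bond * msd_bond)` where
#' `msd_bond` is the mean squared deviation of backbone bond lengths from
#' ideal values (Angstrom^2). With the defaults, stereochemically sound
#' models score below -100 and coordinate-scrambled decoys score far
#' above it, so the standard -100 filter threshold applies unchanged. The
#' score depends only on internal distances and is therefore invariant
#' under rigid motion. Outputs are labelled `internal_fallback` and must
#' not be mixed with external scores in one run.
#'
#' @param model a `structure_model`.
#' @param base offset setting the score of an ideal model (default 125).
#' @param w_clash weight on the clash score (default 0.02).
#' @param w_bond weight on the bond-length MSD, per Angstrom^2
#'   (default 8).
#' @return a `geometry_score` with source `"internal_fallback"`.
#' @export
fallback_geometry_score <- function(model, base = 125, w_clash = 0.02,
                                    w_bond = 8) {
  bonds <- backbone_bonds(model)
  xyz <- atom_coords(model)
  dvec <- xyz[bonds$i, , drop = FALSE] - xyz[bonds$j, , drop = FALSE]
  blen <- sqrt(rowSums(dvec^2))
  msd <- mean((blen - bonds$ideal)^2)
  cs <- clash_score(model)
  nres <- n_residues(model)
  scaled <- -(base - w_clash * cs - w_bond * msd)
  geometry_score(scaled * nres, nres, source = "internal_fallback")
}

#' Score every model of an ensemble with the fallback scorer
#' @param ens an `ensemble`.
#' @param ... passed to [fallback_geometry_score()].
#' @return list of `geometry_score`.
#' @export
score_ensemble <- function(ens, ...) {
  lapply(ens$models, fallback_geometry_score, ...)
}

#' Filter ensemble models by scaled geometry score
#'
#' Keeps models whose scaled score is less than or equal to the
#' threshold ("above the threshold" is discarded; the boundary is kept),
#' preserving the original order. Mixing external and fallback scores is
#' an error because scores are only comparable within one source.
#'
#' @param ens an `ensemble`.
#' @param scores list of `geometry_score`, one per model.
#' @param config a `filter_config`.
#' @return integer indices (1-based) of kept models, in input order.
#' @export
filter_models <- function(ens, scores, config = filter_config()) {
  if (length(scores) != length(ens))
    stop("length mismatch: ", length(scores), " scores for ",
         length(ens), " models")
  src <- unique(vapply(scores, `[[`, "", "source"))
  if (length(src) > 1)
    stop("mixed score sources in one run: ", paste(src, collapse = ", "))
  scaled <- vapply(scores, `[[`, 0, "scaled")
  kept <- which(scaled <= config$threshold)
  if (!length(kept))
    warning("no models pass the scaled-score threshold ", config$threshold)
  kept
}
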