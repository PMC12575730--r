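#' Region specification for RMSD metrics
#'
#' Residue ranges are inclusive, in author numbering, per chain — the
#' convention used when quoting regions of local conformational change
#' (e.g. a single transmembrane helix).
#'
#' @param ranges data.frame with columns `chain`, `start`, `end`
#'   (inclusive), or a list of length-3 vectors.
#' @param align_on `"all_ca"` (superpose on every matched C-alpha, then
#'   report region RMSD — the "local deviation" convention),
#'   `"region"` (superpose on the region itself), or an integer vector of
#'   matched-residue indices (custom scaffold alignment).
#' @return object of class `region_spec`.
#' @export
region_spec <- function(ranges, align_on = "all_ca") {
  if (is.list(ranges) && !is.data.frame(ranges))
    ranges <- do.call(rbind, lapply(ranges, function(r)
      data.frame(chain = as.character(r[1]), start = as.integer(r[2]),
                 end = as.integer(r[3]))))
  stopifnot(nrow(ranges) >= 1, all(ranges$start <= ranges$end))
  structure(list(ranges = ranges, align_on = align_on),
            class = "region_spec")
}

# indices (into the matched-residue set) selected by a region_spec
region_indices <- function(rt, region) {
  sel <- rep(FALSE, nrow(rt))
  for (r in seq_len(nrow(region$ranges))) {
    rr <- region$ranges[r, ]
    sel <- sel | (rt$chain == rr$chain & rt$resno >= rr$start &
                    rt$resno <= rr$end)
  }
  which(sel)
}

# match residues of two models by (chain, resno, insert); returns row
# indices into each model's CA coordinate matrix
match_residues <- function(model_a, model_b) {
  ra <- residue_table(model_a)
  rb <- residue_table(model_b)
  ka <- paste(ra$chain, ra$resno, ra$insert, sep = "\r")
  kb <- paste(rb$chain, rb$resno, rb$insert, sep = "\r")
  ia <- which(ka %in% kb)
  if (!length(ia))
    stop("no residue correspondence; unmatched examples: ",
         paste(utils::head(gsub("\r", "/", ka), 3), collapse = ", "),
         " vs ", paste(utils::head(gsub("\r", "/", kb), 3), collapse = ", "))
  list(a = ia, b = match(ka[ia], kb), table = ra[ia, , drop = FALSE])
}

#' C-alpha RMSD between two models
#'
#' Residues are matched by (chain, residue number, insertion code). With
#' `align = TRUE` the models are first Kabsch-superposed on the subset
#' named by `region$align_on` (default: all matched C-alphas), then the
#' RMSD is evaluated over the region residues; with `align = FALSE` the
#' raw coordinates are compared.
#'
#' @param model_a,model_b `structure_model`s.
#' @param region a `region_spec`, or NULL for all matched residues.
#' @param align superpose before measuring (default TRUE).
#' @return RMSD in Angstrom.
#' @export
ca_rmsd <- function(model_a, model_b, region = NULL, align = TRUE) {
  mm <- match_residues(model_a, model_b)
  ca_a <- ca_coordinates(model_a)[mm$a, , drop = FALSE]
  ca_b <- ca_coordinates(model_b)[mm$b, , drop = FALSE]
  eval_idx <- if (is.null(region)) seq_len(nrow(ca_a))
  else region_indices(mm$table, region)
  if (!length(eval_idx)) stop("region selects no matched residues")
  if (align) {
    align_idx <- if (is.null(region) ||
                     identical(region$align_on, "all_ca"))
      seq_len(nrow(ca_a))
    else if (identical(region$align_on, "region")) eval_idx
    else region$align_on
    ca_a <- apply_transform(superpose(ca_a, ca_b, align_idx)$transform,
                            ca_a)
  }
  sqrt(mean(rowSums((ca_a[eval_idx, , drop = FALSE] -
                       ca_b[eval_idx, , drop = FALSE])^2)))
}

#' Per-residue C-alpha deviation after one global superposition
#'
#' @param model_a,model_b `structure_model`s.
#' @param align_on indices (into the matched set) to superpose on, or
#'   `"all_ca"`.
#' @return named numeric vector of per-residue deviations, Angstrom,
#'   names `chain/resno`.
#' @export
per_residue_deviation <- function(model_a, model_b, align_on = "all_ca") {
  mm <- match_residues(model_a, model_b)
  ca_a <- ca_coordinates(model_a)[mm$a, , drop = FALSE]
  ca_b <- ca_coordinates(model_b)[mm$b, , drop = FALSE]
  idx <- if (identical(align_on, "all_ca")) seq_len(nrow(ca_a))
  else align_on
  ca_a <- apply_transform(superpose(ca_a, ca_b, idx)$transform, ca_a)
  stats::setNames(sqrt(rowSums((ca_a - ca_b)^2)),
                  paste(mm$table$chain, mm$table$resno, sep = "/"))
}
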