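# Additive spectral tuning of LWS (long-wavelength-sensitive) opsins.
#
# The absorbance maximum (lambda-max) of an LWS pigment is largely set by
# five key residues, conventionally numbered against bovine rhodopsin
# (sites 164, 181, 261, 269, 292; the "five-sites rule"). Substitutions at
# these sites shift lambda-max additively relative to an ancestral pigment.

#' Map reference key sites onto a query opsin
#'
#' Either give the query-numbering positions of the key sites directly
#' (`query_sites`), or provide a gapped pairwise alignment of the reference
#' (bovine rhodopsin numbering) and the query, from which the site mapping is
#' derived column-by-column. All numbering is 1-based.
#'
#' @param reference_sites Key sites in reference numbering (default
#'   `c(164, 181, 261, 269, 292)`).
#' @param query_sites Optional key sites in query numbering (same length).
#' @param alignment Optional named character vector or list with elements
#'   `reference` and `query`: equal-length gapped sequences.
#' @return A list of class `key_site_map`.
#' @export
key_site_map <- function(reference_sites = c(164L, 181L, 261L, 269L, 292L),
                         query_sites = NULL, alignment = NULL) {
  if (is.null(query_sites) && is.null(alignment)) {
    stop("provide either query_sites or an alignment")
  }
  if (!is.null(query_sites)) {
    stopifnot(length(query_sites) == length(reference_sites))
  }
  if (!is.null(alignment)) {
    alignment <- as.list(alignment)
    stopifnot(all(c("reference", "query") %in% names(alignment)),
              nchar(alignment$reference) == nchar(alignment$query))
  }
  structure(list(reference_sites = as.integer(reference_sites),
                 query_sites = if (is.null(query_sites)) NULL else as.integer(query_sites),
                 alignment = alignment),
            class = "key_site_map")
}

#' Extract the key tuning residues of a query opsin
#'
#' Returns the query residues at the positions mapped to the reference key
#' sites, as a string of one character per site. A deletion (gap) covering a
#' key site yields `-` in the output with a warning.
#'
#' @param map A [key_site_map()].
#' @param query Optional query sequence (string or single-row sequence
#'   frame); required when `map` carries `query_sites`, ignored when the
#'   mapping comes from the alignment (which already contains the query).
#' @return Character string of key residues (e.g. `"SHYTA"`).
#' @export
extract_key_residues <- function(map, query = NULL) {
  stopifnot(inherits(map, "key_site_map"))
  if (!is.null(map$query_sites)) {
    if (is.null(query)) stop("query sequence required when using query_sites")
    res <- .as_protein(query)$residues
    if (any(map$query_sites > nchar(res))) {
      stop("query site beyond end of sequence")
    }
    out <- paste(substring(res, map$query_sites, map$query_sites),
                 collapse = "")
  } else {
    ref <- strsplit(toupper(map$alignment$reference), "", fixed = TRUE)[[1L]]
    qry <- strsplit(toupper(map$alignment$query), "", fixed = TRUE)[[1L]]
    ref_pos <- cumsum(ref != "-")
    cols <- match(map$reference_sites, ref_pos)
    bad <- ref_pos[length(ref_pos)] < map$reference_sites
    if (any(bad) || anyNA(cols)) {
      stop("reference site ",
           paste(map$reference_sites[is.na(cols) | bad], collapse = ", "),
           " outside the alignment")
    }
    out <- paste(qry[cols], collapse = "")
  }
  if (grepl("-", out, fixed = TRUE)) {
    warning("gap at key tuning site(s): ", out)
  }
  out
}

#' Additive LWS spectral-tuning model
#'
#' Defaults encode the ancestral/human-like LWS pigment: key residues
#' `SHYTA` at bovine-rhodopsin sites 164/181/261/269/292 with a baseline
#' lambda-max of 560 nm, plus the classical five-sites-rule substitution
#' shifts (S164A -7, H181Y -28, Y261F -10, T269A -15, A292S -27 nm). All
#' entries are literature defaults and fully overridable; the Y261F entry is
#' the one exercised by goby LWS paralog comparisons.
#'
#' @param baseline_residues Key residues of the baseline pigment.
#' @param baseline_lambda_max Baseline lambda-max in nm.
#' @param shifts Data frame with columns `site`, `from`, `to`, `delta_nm`.
#' @param reference_sites Key sites in reference numbering.
#' @return A list of class `tuning_model`.
#' @export
tuning_model <- function(baseline_residues = "SHYTA",
                         baseline_lambda_max = 560,
                         shifts = data.frame(
                           site = c(164L, 181L, 261L, 269L, 292L),
                           from = c("S", "H", "Y", "T", "A"),
                           to = c("A", "Y", "F", "A", "S"),
                           delta_nm = c(-7, -28, -10, -15, -27),
                           stringsAsFactors = FALSE),
                         reference_sites = c(164L, 181L, 261L, 269L, 292L)) {
  stopifnot(nchar(baseline_residues) == length(reference_sites),
            all(shifts$site %in% reference_sites))
  structure(list(baseline_residues = toupper(baseline_residues),
                 baseline_lambda_max = baseline_lambda_max,
                 shifts = shifts,
                 reference_sites = as.integer(reference_sites)),
            class = "tuning_model")
}

#' Predict lambda-max from key tuning residues
#'
#' Adds to the baseline lambda-max the shift of every site where the
#' observed residue differs from the baseline residue, looked up in the
#' model's substitution table. Substitutions without a table entry
#' contribute 0 nm and are recorded in the `notes` attribute of the result.
#'
#' @param key_residues String of key residues, one per model site (no gaps).
#' @param model A [tuning_model()].
#' @return Predicted lambda-max in nm (numeric scalar; attribute `notes`
#'   lists unknown substitutions, if any).
#' @export
predict_lambda_max <- function(key_residues, model = tuning_model()) {
  stopifnot(inherits(model, "tuning_model"))
  key_residues <- toupper(key_residues)
  if (nchar(key_residues) != length(model$reference_sites)) {
    stop("expected ", length(model$reference_sites), " key residues, got ",
         nchar(key_residues))
  }
  if (grepl("-", key_residues, fixed = TRUE)) {
    stop("gap in key residues '", key_residues,
         "'; resolve the alignment before prediction")
  }
  obs <- strsplit(key_residues, "", fixed = TRUE)[[1L]]
  base <- strsplit(model$baseline_residues, "", fixed = TRUE)[[1L]]
  lam <- model$baseline_lambda_max
  notes <- character()
  for (i in seq_along(obs)) {
    if (obs[i] == base[i]) next
    site <- model$reference_sites[i]
    row <- which(model$shifts$site == site & model$shifts$from == base[i] &
                   model$shifts$to == obs[i])
    if (length(row) >= 1L) {
      lam <- lam + model$shifts$delta_nm[row[1L]]
    } else {
      notes <- c(notes, sprintf("%s%d%s: no shift entry, contributes 0 nm",
                                base[i], site, obs[i]))
    }
  }
  if (length(notes) > 0L) attr(lam, "notes") <- notes
  lam
}

#' Predicted spectral shift between two opsins
#'
#' Difference of the two predicted lambda-max values,
#' `predict_lambda_max(a) - predict_lambda_max(b)`; antisymmetric in its
#' arguments.
#'
#' @param residues_a,residues_b Key-residue strings for the two pigments.
#' @param model A [tuning_model()].
#' @return Shift in nm (positive when `a` is longer-shifted than `b`).
#' @export
tuning_shift <- function(residues_a, residues_b, model = tuning_model()) {
  as.numeric(predict_lambda_max(residues_a, model)) -
    as.numeric(predict_lambda_max(residues_b, model))
}
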