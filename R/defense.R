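#' Score species-level chemical defense from assay extracts
#'
#' Averages normalized unpalatability (1 - ED50) and toxicity (1 - LD50)
#' indices over a species' whole-body extract assays; non-whole-body rows are
#' dropped before averaging, and a species with no usable rows is reported
#' with missing indices rather than zeros. The per-species record is then
#' classified ([classify_defense()]) and assigned to an analysis group
#' ([assign_defense_group()]).
#'
#' @param assays Data frame with columns `species`, `extract_id`,
#'   `extract_type`, `unpalatability_index`, `toxicity_index`; indices must
#'   already be normalized to `[0, 1]` (1 = least palatable / least toxic
#'   dose needed, i.e. strongest defense).
#' @param boundary_to_lower Passed to [classify_defense()].
#' @return Data frame, one row per species: `species`,
#'   `unpalatability_index`, `toxicity_index`, `n_extracts`,
#'   `defense_class`, `analysis_group`.
#' @export
score_species <- function(assays, boundary_to_lower = TRUE) {
  need <- c("species", "extract_type", "unpalatability_index",
            "toxicity_index")
  if (!all(need %in% names(assays)))
    stop("assay table must have columns: ", paste(need, collapse = ", "))
  out <- do.call(rbind, lapply(split(assays, assays$species), function(d) {
    wb <- d[d$extract_type == "whole_body", , drop = FALSE]
    if (nrow(wb) == 0) {
      data.frame(species = d$species[1],
                 unpalatability_index = NA_real_,
                 toxicity_index = NA_real_, n_extracts = 0L)
    } else {
      data.frame(species = d$species[1],
                 unpalatability_index = mean(wb$unpalatability_index),
                 toxicity_index = mean(wb$toxicity_index),
                 n_extracts = nrow(wb))
    }
  }))
  rownames(out) <- NULL
  out$defense_class <- vapply(out$unpalatability_index, function(x) {
    if (is.na(x)) NA_character_ else classify_defense(x, boundary_to_lower)
  }, character(1))
  out$analysis_group <- mapply(function(cl, tox) {
    if (is.na(cl) || is.na(tox)) NA_character_
    else assign_defense_group(cl, tox)
  }, out$defense_class, out$toxicity_index, USE.NAMES = FALSE)
  out
}

#' Classify an unpalatability index into a defense class
#'
#' Step classification of the normalized unpalatability index: 0 is
#' `palatable`; values up to 0.25 `weakly_unpalatable`; values between 0.25
#' and 0.74 `medium_unpalatable`; 0.74 and higher `highly_unpalatable`
#' (0.74 rather than 0.75 being the median unpalatability among defended
#' species). The 0.25 boundary is read as inclusive to the lower class;
#' set `boundary_to_lower = FALSE` to assign it upward instead.
#'
#' @param index Unpalatability index in `[0, 1]`.
#' @param boundary_to_lower Whether 0.25 belongs to `weakly_unpalatable`
#'   (default) or `medium_unpalatable`.
#' @return One of `"palatable"`, `"weakly_unpalatable"`,
#'   `"medium_unpalatable"`, `"highly_unpalatable"`.
#' @examples
#' classify_defense(0)     # palatable
#' classify_defense(0.25)  # weakly_unpalatable
#' classify_defense(0.74)  # highly_unpalatable
#' @export
classify_defense <- function(index, boundary_to_lower = TRUE) {
  if (!is.numeric(index) || length(index) != 1L || is.na(index) ||
      index < 0 || index > 1)
    stop("'index' must be a single value in [0, 1]")
  if (index == 0) return("palatable")
  if (index >= 0.74) return("highly_unpalatable")
  weak <- if (boundary_to_lower) index <= 0.25 else index < 0.25
  if (weak) "weakly_unpalatable" else "medium_unpalatable"
}

#' Assign the three-level analysis group
#'
#' Groups used by all downstream models: `undefended` (palatable, no known
#' toxicity), `toxic_moderate` (some toxicity, weakly or medium
#' unpalatable), `toxic_high` (some toxicity, highly unpalatable). An
#' inconsistent combination (unpalatable but zero toxicity, or palatable but
#' toxic) has no defined group and errors, flagging the species for manual
#' assignment.
#'
#' @param defense_class A class from [classify_defense()].
#' @param toxicity_index Normalized toxicity index in `[0, 1]`.
#' @return One of `"undefended"`, `"toxic_moderate"`, `"toxic_high"`.
#' @export
assign_defense_group <- function(defense_class, toxicity_index) {
  stopifnot(defense_class %in% c("palatable", "weakly_unpalatable",
                                 "medium_unpalatable", "highly_unpalatable"),
            is.numeric(toxicity_index), toxicity_index >= 0,
            toxicity_index <= 1)
  if (defense_class == "palatable" && toxicity_index == 0) return("undefended")
  if (toxicity_index > 0 &&
      defense_class %in% c("weakly_unpalatable", "medium_unpalatable"))
    return("toxic_moderate")
  if (toxicity_index > 0 && defense_class == "highly_unpalatable")
    return("toxic_high")
  stop("inconsistent defense combination (class = ", defense_class,
       ", toxicity = ", toxicity_index, "): flag for manual assignment")
}
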