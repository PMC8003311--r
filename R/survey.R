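# The nine-point sampling grid and the composite urban quietness index.
#
# A candidate quiet area is sampled at eight points on its edge and one at
# its core. Per-point ACI and NDSI values are combined into:
#   CB     = mean(edge ACI) / core ACI      (complexity balance; 1 = even)
#   RG_ACI = max(ACI) - min(ACI)            (over all nine points)
#   AD     = sign(mean NDSI)                (anthropogenic disturbance)
#   CUQI   = AD * (RG_ACI * CB)
# A positive, high CUQI marks a complex, biophony-dominated acoustic
# environment; a negative score marks anthropogenic dominance.

#' Survey point roles
#'
#' The supported area shape is fixed: eight edge points (`edge1` .. `edge8`)
#' plus one `core` point.
#' @return Character vector of the nine role names.
#' @export
survey_roles <- function() c(paste0("edge", 1:8), "core")

#' Assemble an area survey from per-point index values
#'
#' Validates the nine-point grid: every role exactly once, ACI non-negative,
#' NDSI within \[-1, 1\]. All values must come from identically parameterized
#' analyses of equal-duration clips ([survey_from_clips()] enforces this
#' when starting from audio).
#'
#' @param area_name Area label (non-empty string).
#' @param points Data frame with columns `role`, `clip_ref`, `aci`, `ndsi`.
#' @param params The shared [analysis_params()] set (kept for provenance).
#' @return An object of class `area_survey`.
#' @export
area_survey <- function(area_name, points, params = analysis_params()) {
  if (!is.character(area_name) || length(area_name) != 1L || !nzchar(area_name))
    stop("`area_name` must be a non-empty string")
  need <- c("role", "clip_ref", "aci", "ndsi")
  if (!all(need %in% names(points)))
    stop("`points` must have columns: ", paste(need, collapse = ", "))
  roles <- survey_roles()
  missing <- setdiff(roles, points$role)
  if (length(missing))
    stop("missing role ", paste(missing, collapse = ", "),
         " in area ", area_name)
  if (anyDuplicated(points$role) || nrow(points) != 9L)
    stop("area ", area_name, " must have exactly one point per role")
  if (any(!is.finite(points$aci)) || any(points$aci < 0))
    stop("ACI values must be finite and non-negative (area ", area_name, ")")
  if (any(!is.finite(points$ndsi)) || any(abs(points$ndsi) > 1 + 1e-12))
    stop("NDSI values must lie in [-1, 1] (area ", area_name, ")")
  points <- points[match(roles, points$role), , drop = FALSE]
  rownames(points) <- NULL
  structure(list(area_name = area_name, points = points, params = params),
            class = "area_survey")
}

#' @export
print.area_survey <- function(x, ...) {
  cat(sprintf("<area_survey> %s: mean edge ACI %.4g, core ACI %.4g, mean NDSI %+.3f\n",
              x$area_name, mean(x$points$aci[x$points$role != "core"]),
              x$points$aci[x$points$role == "core"], mean(x$points$ndsi)))
  invisible(x)
}

#' Build a survey from nine audio clips
#'
#' Conditions each clip (mono, shared analysis rate), truncates all nine to
#' the shortest duration — ACI totals scale with frame count, so the ratio
#' and range sub-indices are only meaningful at equal length — and extracts
#' ACI and NDSI per point with the one shared parameter set.
#'
#' @param area_name Area label.
#' @param clips Named list of nine [audio_clip()]s, names being the roles of
#'   [survey_roles()].
#' @param params An [analysis_params()] object.
#' @param clip_refs Optional character vector of recording identifiers
#'   (defaults to the role names).
#' @return An [area_survey()].
#' @export
survey_from_clips <- function(area_name, clips, params = analysis_params(),
                              clip_refs = NULL) {
  roles <- survey_roles()
  missing <- setdiff(roles, names(clips))
  if (length(missing))
    stop("missing role ", paste(missing, collapse = ", "),
         " in area ", area_name)
  clips <- clips[roles]
  if (is.null(clip_refs)) clip_refs <- roles
  conditioned <- truncate_common(
    lapply(clips, condition_clip, analysis_rate = params$analysis_rate))
  vals <- lapply(conditioned, function(cl) {
    sp <- spectrogram(cl, params$window_len, params$hop, params$window)
    c(aci = aci(sp, params$cluster_s)$value,
      ndsi = ndsi(sp, params$anthro_band, params$bio_band)$value)
  })
  pts <- data.frame(role = roles, clip_ref = clip_refs,
                    aci = vapply(vals, `[[`, numeric(1), "aci"),
                    ndsi = vapply(vals, `[[`, numeric(1), "ndsi"),
                    stringsAsFactors = FALSE)
  area_survey(area_name, pts, params)
}

#' Read surveys from a manifest CSV
#'
#' The manifest maps recordings to sampling-point roles, one row per
#' recording, with columns `area_name`, `role` (`edge1` .. `edge8`, `core`)
#' and `wav_path`. Relative paths are resolved against the manifest's own
#' directory.
#'
#' @param manifest_path Path to the manifest CSV.
#' @param params An [analysis_params()] object shared by all areas.
#' @return A named list of [area_survey()]s, one per area.
#' @export
surveys_from_manifest <- function(manifest_path, params = analysis_params()) {
  if (!file.exists(manifest_path))
    stop("cannot read manifest (no such file): ", manifest_path)
  man <- utils::read.csv(manifest_path, stringsAsFactors = FALSE)
  need <- c("area_name", "role", "wav_path")
  if (!all(need %in% names(man)))
    stop("manifest must have columns: ", paste(need, collapse = ", "))
  base <- dirname(manifest_path)
  resolve <- function(p) ifelse(grepl("^(/|[A-Za-z]:)", p), p,
                                file.path(base, p))
  lapply(split(man, man$area_name), function(rows) {
    clips <- lapply(resolve(rows$wav_path), read_wav)
    names(clips) <- rows$role
    survey_from_clips(rows$area_name[1], clips, params,
                      clip_refs = rows$wav_path[match(survey_roles(),
                                                      rows$role)])
  })
}

edge_aci <- function(survey) survey$points$aci[survey$points$role != "core"]
core_aci <- function(survey) survey$points$aci[survey$points$role == "core"]

#' Complexity balance (CB)
#'
#' The ratio of mean edge complexity to core complexity,
#' \eqn{CB = \bar e / c}. A value near 1 indicates complexity evenly
#' distributed over the area; above 1, a core poor in complexity; below 1,
#' edges likely degraded by masking noise. A core with zero ACI signals a
#' broken measurement (not infinite quietness) and is an error.
#'
#' @param survey An [area_survey()].
#' @return CB, a positive scalar.
#' @export
complexity_balance <- function(survey) {
  c_val <- core_aci(survey)
  if (c_val == 0)
    stop("silent core in area ", survey$area_name,
         ": core ACI is 0, complexity balance is undefined")
  mean(edge_aci(survey)) / c_val
}

#' ACI range (RG_ACI)
#'
#' The spread of acoustic complexity over the area:
#' \eqn{RG_{ACI} = ACI_{max} - ACI_{min}} across all nine sampling points,
#' core included.
#'
#' @param survey An [area_survey()].
#' @return A non-negative scalar.
#' @export
aci_range <- function(survey) {
  max(survey$points$aci) - min(survey$points$aci)
}

#' Anthropogenic disturbance sign (AD)
#'
#' The sign of the mean NDSI over the nine points,
#' \eqn{AD = \overline{NDSI} / |\overline{NDSI}|}: +1 when biophony
#' dominates on balance, -1 when anthropophony does. The ratio is undefined
#' at a mean of exactly zero; that boundary is defined here as 0 (neutral),
#' which makes the composite score zero rather than forcing an arbitrary
#' sign.
#'
#' @param survey An [area_survey()].
#' @return -1, 0 or +1.
#' @export
anthropogenic_disturbance <- function(survey) {
  sign(mean(survey$points$ndsi))
}

#' Composite urban quietness index (CUQI)
#'
#' The area-level composite \eqn{CUQI = AD \times (RG_{ACI} \times CB)}:
#' the complexity spread scaled by the edge/core balance, signed by which
#' sound class dominates. Positive and high marks a balanced, complex,
#' biophony-dominated environment; negative marks anthropogenic dominance.
#'
#' @param survey An [area_survey()].
#' @return An object of class `area_score` with fields `area_name`, `cb`,
#'   `rg_aci`, `ad` and `cuqi` (the product of the other three, exactly
#'   recomputable from the stored parts).
#' @export
cuqi <- function(survey) {
  cb <- complexity_balance(survey)
  rg <- aci_range(survey)
  ad <- anthropogenic_disturbance(survey)
  structure(list(area_name = survey$area_name, cb = cb, rg_aci = rg,
                 ad = ad, cuqi = ad * (rg * cb)),
            class = "area_score")
}

#' @export
print.area_score <- function(x, ...) {
  cat(sprintf("<area_score> %s: CUQI %.4g (AD %+d, RG_ACI %.4g, CB %.4g)\n",
              x$area_name, x$cuqi, x$ad, x$rg_aci, x$cb))
  invisible(x)
}

#' Rank areas by CUQI
#'
#' Orders candidate areas from most to least quiet-area-like: descending
#' CUQI, ties broken by lexicographic area name so the ranking is
#' deterministic.
#'
#' @param scores A list of `area_score` objects (from [cuqi()]), or a single
#'   one.
#' @return A data frame with columns `rank` (1-based), `area_name`, `cb`,
#'   `rg_aci`, `ad`, `cuqi`.
#' @export
rank_areas <- function(scores) {
  if (inherits(scores, "area_score")) scores <- list(scores)
  if (!length(scores)) stop("at least one area score is required")
  df <- do.call(rbind, lapply(scores, function(s)
    data.frame(area_name = s$area_name, cb = s$cb, rg_aci = s$rg_aci,
               ad = s$ad, cuqi = s$cuqi, stringsAsFactors = FALSE)))
  if (anyDuplicated(df$area_name))
    stop("duplicate area_name in scores: ",
         paste(unique(df$area_name[duplicated(df$area_name)]), collapse = ", "))
  df <- df[order(-df$cuqi, df$area_name), , drop = FALSE]
  rownames(df) <- NULL
  cbind(rank = seq_len(nrow(df)), df)
}
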