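#' Threshold adapters for competing in-silico scores
#'
#' Published predictors expose their calls in different shapes: a numeric
#' score with a documented cutoff, a categorical verdict vocabulary, or a
#' numeric score with an "uncertain" middle band. A `threshold_rule`
#' normalizes any of them to the D / ND / uncertain vocabulary so they can
#' run through the same validation harnesses as the model.
#'
#' @param score Score name.
#' @param mode `"numeric_cutoff"`, `"category_map"` or
#'   `"cutoff_with_uncertain_band"`.
#' @param cutoff Numeric cutoff (numeric mode), or length-2 `c(lower,
#'   upper)` band (uncertain-band mode: scores inside the open band are
#'   uncertain).
#' @param direction `"higher_deleterious"` (default) or
#'   `"lower_deleterious"`; the deleterious side of a cutoff is inclusive.
#' @param map Named character vector category -> `"D"`/`"ND"`
#'   (category-map mode); must cover the score's vocabulary.
#' @return Object of class `threshold_rule`.
#' @examples
#' revel_b <- threshold_rule("REVEL", "numeric_cutoff", cutoff = 0.5)
#' classify_by_threshold(data.frame(variant = "v1", score = 0.6), revel_b)
#' @export
threshold_rule <- function(score,
                           mode = c("numeric_cutoff", "category_map",
                                    "cutoff_with_uncertain_band"),
                           cutoff = NULL, direction = "higher_deleterious",
                           map = NULL) {
  mode <- match.arg(mode)
  direction <- match.arg(direction,
                         c("higher_deleterious", "lower_deleterious"))
  if (mode == "numeric_cutoff") {
    stopifnot(is.numeric(cutoff), length(cutoff) == 1L, is.finite(cutoff))
  } else if (mode == "cutoff_with_uncertain_band") {
    stopifnot(is.numeric(cutoff), length(cutoff) == 2L, all(is.finite(cutoff)),
              cutoff[1] <= cutoff[2])
  } else {
    stopifnot(!is.null(map), all(map %in% c("D", "ND")))
  }
  structure(list(score = score, mode = mode, cutoff = cutoff,
                 direction = direction, map = map),
            class = "threshold_rule")
}

#' Apply a threshold rule to a score table
#'
#' @param scores data.frame with columns `variant` and `score` (numeric or
#'   categorical, matching the rule's mode).
#' @param rule A [threshold_rule()].
#' @return data.frame `variant`, `class` in `{D, ND, uncertain}`; missing
#'   scores are `uncertain`.
#' @export
classify_by_threshold <- function(scores, rule) {
  stopifnot(inherits(rule, "threshold_rule"))
  scores <- as.data.frame(scores)
  require_columns(scores, c("variant", "score"), "score table")
  s <- scores$score
  cls <- rep("uncertain", length(s))
  obs <- !is.na(s)
  if (rule$mode == "category_map") {
    unknown <- obs & !(s %in% names(rule$map))
    if (any(unknown)) {
      stop("category outside the rule vocabulary for '", rule$score, "': ",
           paste(unique(s[unknown]), collapse = ", "))
    }
    cls[obs] <- unname(rule$map[s[obs]])
  } else {
    s <- as.numeric(s)
    flip <- rule$direction == "lower_deleterious"
    if (rule$mode == "numeric_cutoff") {
      del <- if (flip) s <= rule$cutoff else s >= rule$cutoff
      cls[obs] <- ifelse(del[obs], "D", "ND")
    } else {
      lo <- rule$cutoff[1]
      hi <- rule$cutoff[2]
      in_band <- s > lo & s < hi
      del <- if (flip) s <= lo else s >= hi
      cls[obs & !in_band] <- ifelse(del[obs & !in_band], "D", "ND")
    }
  }
  data.frame(variant = scores$variant, class = cls, stringsAsFactors = FALSE)
}

#' Built-in threshold rules for published predictors
#'
#' The documented cutoffs of commonly compared tools: two REVEL cutoffs
#' (0.5 and 0.7), the generic and TP53-truthset CHASM cutoffs (0.768,
#' 0.892), the PolyPhen and MutationAssessor category maps, and generic
#' uncertain-band wrappers for EVE-style scores.
#'
#' @return Named list of [threshold_rule()] objects.
#' @export
default_threshold_rules <- function() {
  list(
    Revel_b = threshold_rule("REVEL", "numeric_cutoff", cutoff = 0.5),
    Revel_c = threshold_rule("REVEL", "numeric_cutoff", cutoff = 0.7),
    CHASM = threshold_rule("CHASM", "numeric_cutoff", cutoff = 0.768),
    CHASM_TP53 = threshold_rule("CHASM", "numeric_cutoff", cutoff = 0.892),
    Polyphen = threshold_rule(
      "Polyphen", "category_map",
      map = c("probably damaging" = "D", "possibly damaging" = "D",
              "benign" = "ND")
    ),
    Mutassessor = threshold_rule(
      "MutationAssessor", "category_map",
      map = c(high = "D", medium = "D", low = "ND", neutral = "ND")
    )
  )
}
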