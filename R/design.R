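#' Rank network modules
#'
#' Orders modules as candidate sources of a functional core microbiome,
#' either by their condition score for a favorable sample condition or by
#' the mean / summed functional coreness of their members. Ties are broken
#' by smaller module id.
#'
#' @param criterion `"condition_score"`, `"mean_coreness"` or
#'   `"sum_coreness"`.
#' @param modScores data.frame from [moduleConditionScores()] (required
#'   for `condition_score`).
#' @param scores a [ScoreTable-class] with module ids (required for the
#'   coreness criteria).
#' @param favorableCondition condition label to rank by (required for
#'   `condition_score`).
#' @return data.frame with columns `rank`, `module`, `value` in
#'   descending order of the criterion.
#' @export
rankModules <- function(criterion = c("condition_score", "mean_coreness",
                                      "sum_coreness"),
                        modScores = NULL, scores = NULL,
                        favorableCondition = NULL) {
  criterion <- match.arg(criterion)
  if (criterion == "condition_score") {
    if (is.null(modScores))
      stop("criterion 'condition_score' needs modScores")
    if (is.null(favorableCondition))
      stop("criterion 'condition_score' needs a favorable condition label")
    if (!favorableCondition %in% modScores$condition)
      stop("unknown condition label: '", favorableCondition, "'")
    sub <- modScores[modScores$condition == favorableCondition, ,
                     drop = FALSE]
    val <- stats::setNames(sub$s_module, sub$module)
  } else {
    if (is.null(scores)) stop("coreness criteria need a ScoreTable")
    df <- as.data.frame(scores)
    if (all(is.na(df$module)))
      stop("ScoreTable has no module assignment")
    fun <- if (criterion == "mean_coreness") mean else sum
    agg <- tapply(df$C_func, df$module, fun)
    val <- stats::setNames(as.numeric(agg), names(agg))
  }
  ord <- order(-val, as.integer(names(val)))
  data.frame(rank = seq_along(ord),
             module = as.integer(names(val))[ord],
             value = unname(val)[ord])
}

#' Select a candidate functional core microbiome from a module
#'
#' Members of the chosen module are ordered by descending functional
#' coreness. The `"knee"` rule adds taxa from the top until the score
#' decreases disruptively: the cut is placed before the largest relative
#' successive drop `(C_r - C_{r+1}) / C_r`, considering ranks `r >= 2`
#' with `C_r > 0` so that a set has at least two members. If no positive
#' drop exists (e.g. all scores equal) the whole module is returned with a
#' warning; if the module has fewer than two positive-score members the
#' rule falls back to all positive-score members with a warning. The
#' `"top_k"` rule returns the first `k` members (`k >= 2`).
#'
#' @param scores a [ScoreTable-class] with module ids.
#' @param module module id to draw from.
#' @param rule `"knee"` (default) or `"top_k"`.
#' @param k set size for `"top_k"`.
#' @return A [CoreSet-class]; the member order is a prefix of the module's
#'   full coreness ranking and independent of the input row order.
#' @export
selectCoreSet <- function(scores, module, rule = c("knee", "top_k"),
                          k = NULL) {
  rule <- match.arg(rule)
  df <- as.data.frame(scores)
  df <- df[!is.na(df$module) & df$module == module, , drop = FALSE]
  if (nrow(df) == 0L) stop("no such module in the score table: ", module)
  df <- df[order(-df$C_func, df$taxon), , drop = FALSE]
  cf <- df$C_func
  m <- nrow(df)
  params <- list()
  if (rule == "top_k") {
    if (is.null(k) || k < 2) stop("top_k needs k >= 2")
    if (k > m) {
      warning("k = ", k, " exceeds module size ", m, "; returning all ",
              m, " members")
      k <- m
    }
    take <- seq_len(k)
    params$k <- as.integer(k)
  } else {
    nPos <- sum(cf > 0)
    if (nPos < 2L) {
      warning("module ", module, " has fewer than 2 positive-score ",
              "members; returning all positive-score members")
      take <- which(cf > 0)
      params$fallback <- "all_positive"
    } else {
      cand <- seq(2L, m - 1L)
      cand <- cand[cf[cand] > 0]
      drops <- (cf[cand] - cf[cand + 1L]) / cf[cand]
      params$candidate_ranks <- as.integer(cand)
      params$relative_drops <- drops
      if (length(cand) == 0L || max(drops) <= 0) {
        warning("no disruptive decrease in module ", module,
                "; returning the entire module")
        take <- seq_len(m)
      } else {
        cut <- cand[which.max(drops)]
        params$cut_rank <- as.integer(cut)
        take <- seq_len(cut)
      }
    }
  }
  new("CoreSet", module = as.integer(module), taxa = df$taxon[take],
      cfunc = cf[take], rule = rule, parameters = params)
}
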