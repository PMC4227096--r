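#' Conditioned-place-preference score
#'
#' The CPP score is the fraction of session time spent in the drug-paired
#' compartment. By default the denominator is the total time in the apparatus
#' (both compartments plus the passage); `include_passage = FALSE` restricts
#' it to the two compartments.
#'
#' @param drug_s,saline_s,passage_s seconds in the drug-paired compartment,
#'   the saline-paired compartment and the passage (vectorized).
#' @param include_passage include passage time in the denominator.
#' @return numeric vector of scores in \[0,1\].
#' @export
cpp_score <- function(drug_s, saline_s, passage_s = 0,
                      include_passage = TRUE) {
  if (any(c(drug_s, saline_s, passage_s) < 0))
    stop("negative session times", call. = FALSE)
  total <- drug_s + saline_s + if (include_passage) passage_s else 0
  if (any(total <= 0)) stop("zero total session time", call. = FALSE)
  drug_s / total
}

#' Screen animals for strong unconditioned preference
#'
#' An animal is excluded when it spent more than `threshold` seconds
#' (strictly) in either compartment during the pre-conditioning phase.
#'
#' @param sessions session table (`animal_id`, `phase`, `drug_s`,
#'   `saline_s`).
#' @param threshold exclusion threshold in seconds (default 540).
#' @return data.frame: `animal_id`, `excluded`, `max_compartment_s`.
#' @export
screen_unconditioned_preference <- function(sessions, threshold = 540) {
  pre <- sessions[sessions$phase == "pre", , drop = FALSE]
  if (nrow(pre) == 0) stop("no pre-conditioning sessions", call. = FALSE)
  mx <- pmax(pre$drug_s, pre$saline_s)
  data.frame(animal_id = pre$animal_id,
             excluded = mx > threshold,
             max_compartment_s = mx,
             stringsAsFactors = FALSE)
}

#' Test for conditioned place preference per group
#'
#' Computes per-animal CPP scores for both phases and, per group, a paired
#' two-sided t-test of post- vs pre-conditioning scores (same animals in both
#' phases). Groups are also summarized as mean and SD per phase. If every
#' animal's score is unchanged, the test is degenerate with `p = 1`.
#'
#' @param sessions session table (`animal_id`, `group`, `phase`, `drug_s`,
#'   `saline_s`, `passage_s`) with both phases per animal.
#' @param include_passage passed to [cpp_score()].
#' @return list: `scores` (per animal: `pre`, `post`), `summary` (per group
#'   and phase: `n`, `mean`, `sd`), `tests` (per group: `t`, `df`, `p`,
#'   `degenerate`).
#' @export
assess_preference <- function(sessions, include_passage = TRUE) {
  sessions$score <- cpp_score(sessions$drug_s, sessions$saline_s,
                              sessions$passage_s, include_passage)
  wide <- merge(
    sessions[sessions$phase == "pre", c("animal_id", "group", "score")],
    sessions[sessions$phase == "post", c("animal_id", "score")],
    by = "animal_id", suffixes = c("_pre", "_post"))
  names(wide)[names(wide) == "score_pre"] <- "pre"
  names(wide)[names(wide) == "score_post"] <- "post"
  if (nrow(wide) < 2) stop("need >= 2 animals with both phases", call. = FALSE)

  groups <- unique(wide$group)
  summ <- do.call(rbind, lapply(groups, function(g) {
    w <- wide[wide$group == g, ]
    data.frame(group = g, phase = c("pre", "post"), n = nrow(w),
               mean = c(mean(w$pre), mean(w$post)),
               sd = c(stats::sd(w$pre), stats::sd(w$post)),
               stringsAsFactors = FALSE)
  }))
  tests <- do.call(rbind, lapply(groups, function(g) {
    w <- wide[wide$group == g, ]
    if (nrow(w) < 2)
      stop(sprintf("group %s has fewer than 2 complete animals", g),
           call. = FALSE)
    d <- w$post - w$pre
    if (stats::sd(d) == 0) {
      data.frame(group = g, t = if (mean(d) == 0) 0 else sign(mean(d)) * Inf,
                 df = nrow(w) - 1,
                 p = if (mean(d) == 0) 1 else 0, degenerate = TRUE,
                 stringsAsFactors = FALSE)
    } else {
      tt <- stats::t.test(w$post, w$pre, paired = TRUE)
      data.frame(group = g, t = unname(tt$statistic),
                 df = unname(tt$parameter), p = tt$p.value,
                 degenerate = FALSE, stringsAsFactors = FALSE)
    }
  }))
  rownames(summ) <- rownames(tests) <- NULL
  list(scores = wide, summary = summ, tests = tests)
}
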