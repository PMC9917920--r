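#' Reweight a seed population to regional marginal targets by linear
#' programming
#'
#' Localization: given an arbitrary seed population of agents (for example a
#' synthetic population built for another country), find nonnegative
#' per-cell weights that minimize the total absolute deviation between the
#' weighted seed marginals (sex and condition counts) and the regional
#' targets, subject to the weights summing to the regional patient total.
#'
#' The L1 objective is linearized with split deviation variables and the
#' resulting linear program is solved with a simplex method
#' (`pracma::linprog`). Agents are pooled into (sex x condition) cells first;
#' the returned weight vector is per cell, and per-agent weights follow by
#' dividing equally within a cell.
#'
#' @param seed_population data.frame with at least `sex`, `condition` (one
#'   row per agent; any existing `weight` column is ignored).
#' @param targets a [marginal_target_set()].
#' @return an object of class `weight_vector`: list with `cells` (data.frame
#'   of `sex`, `condition`, `n_seed`, `weight` = total weight for the cell),
#'   `agent_weight` (per-agent weight per cell), and `objective_value`
#'   (achieved L1 marginal deviation, in patients).
#' @examples
#' seed <- data.frame(sex = c("male", "female"), condition = c("UC", "UC"))
#' tg <- regional_targets("tokyo")
#' @export
localize_weights <- function(seed_population, targets) {
  stopifnot(inherits(targets, "marginal_target_set"))
  if (is.null(seed_population) || nrow(seed_population) == 0) {
    stop("seed population is empty", call. = FALSE)
  }
  sex_t <- targets$total_patients * targets$sex_proportions
  cond_t <- targets$total_patients * targets$condition_proportions
  for (s in names(sex_t)) {
    if (sex_t[[s]] > 0 && !any(seed_population$sex == s)) {
      stop(sprintf("target category with zero seed support: sex=%s", s),
           call. = FALSE)
    }
  }
  for (cc in names(cond_t)) {
    if (cond_t[[cc]] > 0 && !any(seed_population$condition == cc)) {
      stop(sprintf("target category with zero seed support: condition=%s", cc),
           call. = FALSE)
    }
  }

  cells <- unique(seed_population[, c("sex", "condition")])
  cells <- cells[order(match(cells$sex, c("male", "female")),
                       match(cells$condition, c("UC", "CD"))), , drop = FALSE]
  rownames(cells) <- NULL
  k <- nrow(cells)
  cells$n_seed <- vapply(seq_len(k), function(i) {
    sum(seed_population$sex == cells$sex[i] &
        seed_population$condition == cells$condition[i])
  }, numeric(1))

  # marginal rows: male, female, UC, CD counts
  A_marg <- rbind(
    as.numeric(cells$sex == "male"),
    as.numeric(cells$sex == "female"),
    as.numeric(cells$condition == "UC"),
    as.numeric(cells$condition == "CD")
  )
  tvec <- c(sex_t[["male"]], sex_t[["female"]], cond_t[["UC"]], cond_t[["CD"]])
  m <- nrow(A_marg)

  # variables: w (k), e_plus (m), e_minus (m)
  # min sum(e_plus + e_minus)
  # s.t. A w - e_plus + e_minus = t ; sum(w) = total ; all vars >= 0
  cc <- c(rep(0, k), rep(1, 2 * m))
  Aeq <- rbind(
    cbind(A_marg, -diag(m), diag(m)),
    c(rep(1, k), rep(0, 2 * m))
  )
  beq <- c(tvec, targets$total_patients)
  sol <- pracma::linprog(cc, A = NULL, b = NULL, Aeq = Aeq, beq = beq,
                         maxiter = 200 + 20 * k)
  if (is.null(sol$x)) {
    stop("linear program for localization did not converge", call. = FALSE)
  }
  w <- pmax(sol$x[seq_len(k)], 0)
  # renormalize away solver round-off so the total is met exactly
  w <- w * targets$total_patients / sum(w)
  obj <- sum(abs(as.numeric(A_marg %*% w) - tvec))
  # the optimum can be degenerate; among equally good solutions prefer the
  # uniform scaling of the seed (least distortion of its composition)
  w_unif <- cells$n_seed * targets$total_patients / sum(cells$n_seed)
  obj_unif <- sum(abs(as.numeric(A_marg %*% w_unif) - tvec))
  if (obj_unif <= obj + 1e-9 * targets$total_patients) {
    w <- w_unif
    obj <- obj_unif
  }
  cells$weight <- w
  structure(
    list(cells = cells,
         agent_weight = w / pmax(cells$n_seed, 1),
         objective_value = obj,
         targets = tvec),
    class = "weight_vector"
  )
}
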