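# Independent oracles used across the suite. Each one deliberately takes a
# different route than the implementation it checks.

# Boolean-rule oracle: translate the rule text into an R logical expression
# and evaluate it under a gene -> TRUE/FALSE assignment. Shares nothing with
# the package's recursive-descent parser/evaluator.
gpr_oracle_eval <- function(rule_text, assignment) {
  expr <- gsub("\\band\\b", "&", rule_text, ignore.case = TRUE)
  expr <- gsub("\\bor\\b", "|", expr, ignore.case = TRUE)
  eval(parse(text = expr), envir = as.list(assignment))
}

# All 2^k gene-state assignments for a gene set
all_assignments <- function(genes) {
  grid <- expand.grid(rep(list(c(TRUE, FALSE)), length(genes)))
  names(grid) <- genes
  grid
}

# LP producibility/consumability oracle for the dead-end definition: optimise
# the net production rate of one metabolite subject to flux bounds alone
# ("under any admissible flux direction" -- deliberately no steady-state
# constraint, which is what makes a *root* dead-end).
lp_gap_oracle <- function(model, tol = 1e-9) {
  S <- stoich_matrix(model)
  lb <- model$reactions$lower_bound
  ub <- model$reactions$upper_bound
  ex_mets <- unique(model$stoichiometry$metabolite[
    model$stoichiometry$reaction %in%
      model$reactions$id[model$reactions$is_exchange]])
  no_prod <- character(); no_cons <- character()
  for (mid in model$metabolites$id) {
    row <- S[mid, ]
    up <- gsmmtools:::solve_lp(row, lb = lb, ub = ub, maximize = TRUE)
    dn <- gsmmtools:::solve_lp(row, lb = lb, ub = ub, maximize = FALSE)
    if (up$objective < tol) no_prod <- c(no_prod, mid)
    if (dn$objective > -tol) no_cons <- c(no_cons, mid)
  }
  list(no_production = sort(setdiff(no_prod, ex_mets)),
       no_consumption = sort(setdiff(no_cons, ex_mets)))
}

# Character-walk formula parser: no regular expressions, one pass over the
# string, used to cross-check parse_formula().
formula_oracle <- function(formula) {
  chars <- strsplit(formula, "")[[1]]
  counts <- integer(); elem <- ""; digits <- ""
  flush <- function() {
    if (elem == "") return()
    n <- if (digits == "") 1L else as.integer(digits)
    counts[elem] <<- (if (elem %in% names(counts)) counts[[elem]] else 0L) + n
  }
  for (ch in chars) {
    if (ch >= "A" && ch <= "Z") {
      flush(); elem <- ch; digits <- ""
    } else if (ch >= "a" && ch <= "z") {
      elem <- paste0(elem, ch)
    } else if (ch >= "0" && ch <= "9") {
      digits <- paste0(digits, ch)
    } else {
      stop("bad char")
    }
  }
  flush()
  counts
}

# Brute-force essentiality: disable reactions through exhaustive truth-table
# evaluation of the rule text, then solve with the enumeration LP.
essentiality_oracle <- function(model, eps_zero = 1e-6, delta = 1e-3) {
  wt <- fba_brute_force(model)$objective
  rows <- lapply(model$genes, function(g) {
    m <- model
    for (rid in m$reactions$id) {
      rule <- m$reactions$gpr[m$reactions$id == rid]
      if (!nzchar(rule)) next
      genes <- gpr_genes(parse_gpr(rule))
      state <- stats::setNames(!(genes %in% g), genes)
      if (!gpr_oracle_eval(rule, state)) {
        m$reactions$lower_bound[m$reactions$id == rid] <- 0
        m$reactions$upper_bound[m$reactions$id == rid] <- 0
      }
    }
    sol <- fba_brute_force(m)
    mu <- if (sol$status == "optimal") max(0, sol$objective) else 0
    cls <- if (mu < eps_zero) "essential"
           else if (mu >= (1 - delta) * wt) "non_essential"
           else "partially_essential"
    tibble::tibble(gene = g, mu_ko = mu, class = cls)
  })
  dplyr::bind_rows(rows)
}

# Textbook Pearson correlation, written out longhand.
pearson_oracle <- function(x, y) {
  mx <- sum(x) / length(x); my <- sum(y) / length(y)
  sum((x - mx) * (y - my)) /
    sqrt(sum((x - mx)^2) * sum((y - my)^2))
}
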