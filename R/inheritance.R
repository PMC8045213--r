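# Classify each tetraploid gene's total expression relative to its two
# parents into the twelve-state inheritance scheme plus "conserved", from the
# three ternary DE calls (T vs S, T vs C, S vs C).

# The full decision table over the 27 ternary triples. Roman numerals are
# stable internal labels for the states within each group; reported statistics
# are at the group level. 13 triples are assignable; the remaining 14 are
# statistically inconsistent and map to "unassigned".
inheritance_decision_table <- function() {
  rows <- rbind(
    c("equal", "equal", "equal", "conserved",  "conserved"),
    # T strictly between differing parents
    c("down",  "up",    "up",    "I",          "intermediate"),        # S > T > C
    c("up",    "down",  "down",  "XII",        "intermediate"),        # C > T > S
    # T equal to C, different from S, parents differing (C-dominance)
    c("up",    "equal", "down",  "II",         "C_dominance"),         # T = C > S
    c("down",  "equal", "up",    "XI",         "C_dominance"),         # S > T = C
    # T equal to S, different from C, parents differing (S-dominance)
    c("equal", "up",    "up",    "IV",         "S_dominance"),         # T = S > C
    c("equal", "down",  "down",  "IX",         "S_dominance"),         # C > T = S
    # T above both parents
    c("up",    "up",    "up",    "V",          "transgressive_up"),    # T > S > C
    c("up",    "up",    "equal", "VI",         "transgressive_up"),    # T > S = C
    c("up",    "up",    "down",  "VIII",       "transgressive_up"),    # T > C > S
    # T below both parents
    c("down",  "down",  "up",    "III",        "transgressive_down"),  # S > C > T
    c("down",  "down",  "equal", "VII",        "transgressive_down"),  # S = C > T
    c("down",  "down",  "down",  "X",          "transgressive_down")   # C > S > T
  )
  df <- as.data.frame(rows, stringsAsFactors = FALSE)
  names(df) <- c("t_vs_s", "t_vs_c", "s_vs_c", "state", "group")
  df
}

#' Classify inheritance of expression from three ternary DE calls
#'
#' Inputs are the up/down/equal calls of the tetraploid against each parent
#' and of parent S against parent C (first argument "up" means the first
#' member of the contrast is higher). The mapping is a total, deterministic
#' decision table: `conserved` for all-equal; `intermediate` (states I, XII)
#' when the tetraploid sits strictly between differing parents;
#' expression-level dominance toward S (IV, IX) or C (II, XI) when the
#' tetraploid equals one parent and differs from the other; transgressive up
#' (V, VI, VIII) or down (III, VII, X) when it lies above or below both; the
#' 14 remaining, statistically inconsistent triples are `unassigned`.
#'
#' @param t_vs_s,t_vs_c,s_vs_c character vectors over
#'   `c("up", "down", "equal")`.
#' @return data.frame: t_vs_s, t_vs_c, s_vs_c, state, group.
#' @export
classify_inheritance <- function(t_vs_s, t_vs_c, s_vs_c) {
  ok <- c("up", "down", "equal")
  if (!all(c(t_vs_s, t_vs_c, s_vs_c) %in% ok))
    hs_stop("classify_inheritance: calls must be one of up/down/equal")
  tab <- inheritance_decision_table()
  key <- paste(t_vs_s, t_vs_c, s_vs_c)
  idx <- match(key, paste(tab$t_vs_s, tab$t_vs_c, tab$s_vs_c))
  data.frame(
    t_vs_s = t_vs_s, t_vs_c = t_vs_c, s_vs_c = s_vs_c,
    state = ifelse(is.na(idx), "unassigned", tab$state[idx]),
    group = ifelse(is.na(idx), "unassigned", tab$group[idx]),
    stringsAsFactors = FALSE
  )
}

INHERITANCE_GROUPS <- c("conserved", "intermediate", "S_dominance", "C_dominance",
                        "transgressive_up", "transgressive_down", "unassigned")

#' Summarize inheritance calls
#'
#' Counts and percentages per state and per category group. The percentage
#' denominator is all classified (expressed) genes, conserved included.
#'
#' @param calls data.frame from [classify_inheritance()].
#' @return list: `by_state` and `by_group` data.frames (count, percent),
#'   `n` total classified genes.
#' @export
summarize_inheritance <- function(calls) {
  n <- nrow(calls)
  states <- c(inheritance_decision_table()$state, "unassigned")
  by_state <- data.frame(
    state = states,
    count = as.integer(table(factor(calls$state, levels = states))),
    stringsAsFactors = FALSE
  )
  by_state$percent <- if (n > 0) 100 * by_state$count / n else 0
  by_group <- data.frame(
    group = INHERITANCE_GROUPS,
    count = as.integer(table(factor(calls$group, levels = INHERITANCE_GROUPS))),
    stringsAsFactors = FALSE
  )
  by_group$percent <- if (n > 0) 100 * by_group$count / n else 0
  list(by_state = by_state, by_group = by_group, n = n)
}
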