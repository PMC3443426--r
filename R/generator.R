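#' Generate a random Boolean network model
#'
#' Builds benchmark-style random networks on a node-count x connectivity
#' grid: every internal node receives exactly `connectivity` distinct
#' regulators drawn uniformly from the other species (self-loops excluded
#' unless enabled). Two rule styles are available:
#'
#' * `"truth_function"` (default): a uniformly random Boolean function of the
#'   regulators, sampled as a random output column over all `2^k` assignments
#'   (supported for `connectivity` up to 20).
#' * `"bio_logic"`: regulators are randomly partitioned into activators and
#'   inhibitors (at least one activator) and grouped into random clauses,
#'   exercising the bio-logic compiler.
#'
#' The result is fully reproducible from `seed` and always passes
#' [validate_model()].
#'
#' @param n_nodes Total species count.
#' @param connectivity Regulators per internal node (`k`); must satisfy
#'   `k <= n_nodes - 1`.
#' @param n_external Number of external input nodes (default 10% of
#'   `n_nodes`, at least 1; must leave at least one internal node).
#' @param seed Integer seed (default 1).
#' @param rule_style `"truth_function"` or `"bio_logic"`.
#' @param allow_self_loops Permit a node among its own regulators (default
#'   `FALSE`).
#' @return A `boolean_model` with species `ext_1..` and `v_1..`.
#' @examples
#' m <- generate_random_model(10, 2, seed = 42)
#' species(m)
#' @export
generate_random_model <- function(n_nodes, connectivity,
                                  n_external = max(1L, round(0.1 * n_nodes)),
                                  seed = 1L,
                                  rule_style = c("truth_function", "bio_logic"),
                                  allow_self_loops = FALSE) {
  n_nodes <- as.integer(n_nodes)
  k <- as.integer(connectivity)
  n_external <- as.integer(n_external)
  rule_style <- match.arg(rule_style)
  if (n_nodes < 2L) stop("infeasible spec: need at least 2 nodes", call. = FALSE)
  if (k < 1L || k > n_nodes - 1L) {
    stop("infeasible spec: connectivity must satisfy 1 <= k <= n_nodes - 1",
         call. = FALSE)
  }
  if (n_external < 0L || n_external >= n_nodes) {
    stop("infeasible spec: n_external must leave at least one internal node",
         call. = FALSE)
  }
  if (rule_style == "truth_function" && k > 20L) {
    stop("infeasible spec: truth_function rules capped at connectivity 20",
         call. = FALSE)
  }
  set.seed(as.integer(seed))
  ext <- if (n_external > 0L) paste0("ext_", seq_len(n_external)) else character()
  int <- paste0("v_", seq_len(n_nodes - n_external))
  all_sp <- c(ext, int)
  rules <- lapply(int, function(tgt) {
    pool <- if (allow_self_loops) all_sp else setdiff(all_sp, tgt)
    regs <- sample(pool, k)
    if (rule_style == "truth_function") {
      # uniform over all 2^(2^k) Boolean functions via a random output column
      truthfn_rule(tgt, regs, stats::runif(2^k) < 0.5)
    } else {
      n_act <- sample(seq_len(k), 1L)
      act <- regs[seq_len(n_act)]
      inh <- if (n_act < k) regs[(n_act + 1L):k] else character()
      split_clauses <- function(members) {
        if (length(members) == 0L) return(list())
        g <- sort(sample(seq_along(members), length(members), replace = TRUE))
        unname(split(members, g))
      }
      biologic_rule(tgt, split_clauses(act), split_clauses(inh))
    }
  })
  names(rules) <- int
  boolean_model(sprintf("random_n%d_k%d_seed%d", n_nodes, k, as.integer(seed)),
                rules, external = ext)
}

#' Canonical small regulatory motifs
#'
#' A library of well-understood toy models used throughout testing and in
#' examples, each with documented synchronous behaviour:
#'
#' * `pass_through`: `Z = X`; Z tracks the input one step delayed.
#' * `inverter`: `Z = NOT X`; Z complements the input.
#' * `and_gate` / `or_gate`: `Z = X AND Y` / `Z = X OR Y`.
#' * `chain`: activator chain `X -> A -> B -> Z`.
#' * `positive_feedback`: `A = B`, `B = A`; two fixed points (both OFF, both
#'   ON) plus the 2-cycle `01 <-> 10` — a memory element.
#' * `negative_feedback_ring`: `A = NOT C`, `B = A`, `C = B`; the classic
#'   ring oscillator. Synchronous dynamics partition the 8 states into a
#'   6-cycle (reached from all-OFF) and a 2-cycle (`010 <-> 101`); in either
#'   attractor every species sits at exactly 50 %ON.
#'
#' @return Named list of `boolean_model` objects.
#' @export
motif_library <- function() {
  list(
    pass_through = boolean_model("pass_through", rules = list(Z = "X")),
    inverter = boolean_model("inverter", rules = list(Z = "NOT X")),
    and_gate = boolean_model("and_gate", rules = list(Z = "X AND Y")),
    or_gate = boolean_model("or_gate", rules = list(Z = "X OR Y")),
    chain = boolean_model("chain",
                          rules = list(A = "X", B = "A", Z = "B")),
    positive_feedback = boolean_model("positive_feedback",
                                      rules = list(A = "B", B = "A")),
    negative_feedback_ring = boolean_model("negative_feedback_ring",
                                           rules = list(A = "NOT C", B = "A",
                                                        C = "B"))
  )
}
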