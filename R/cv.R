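#' Random five-fold group assignment
#'
#' Partitions individuals uniformly at random into `k` near-equal groups
#' (sizes differ by at most one). Each group serves as validation set once.
#'
#' @param individual_ids character or integer labels.
#' @param k number of groups (default 5).
#' @param seed integer seed; the partition is deterministic given the seed.
#' @return A `group_assignment`: list with `group_of` (named integer vector
#'   of labels in `1..k`), `k` and `seed`.
#' @export
assign_groups <- function(individual_ids, k = 5L, seed = 1L) {
  n <- length(individual_ids)
  k <- as.integer(k)
  if (k < 2L) stop("k must be at least 2")
  if (n < k) stop("need at least ", k, " individuals for ", k, " groups")
  sizes <- rep(n %/% k, k) + (seq_len(k) <= n %% k)
  perm <- withr::with_seed(as.integer(seed), sample.int(n))
  g <- integer(n)
  g[perm] <- rep(seq_len(k), times = sizes)
  names(g) <- as.character(individual_ids)
  structure(list(group_of = g, k = k, seed = as.integer(seed)),
            class = "group_assignment")
}

cyc <- function(g, offset, k) ((g - 1L + offset) %% k) + 1L

#' Reference groups for a cross-validation scenario
#'
#' Given the validation group, returns the reference groups under the
#' rotation design: `S80` uses all four other groups, `S60` the three
#' cyclically following groups, `S40` the two following groups, and
#' `TWO_STEP` uses the two following groups as step-1 reference (imputation
#' to the intermediate panel) and the two preceding groups as step-2
#' reference (imputation to sequence). Group arithmetic is modulo `k` on
#' labels `1..k`, so group 5 is followed by group 1.
#'
#' @param scenario one of `"S80"`, `"S60"`, `"S40"`, `"TWO_STEP"`.
#' @param validation_group group label in `1..k`.
#' @param k number of groups (default 5).
#' @return For single-step scenarios an integer vector of reference groups;
#'   for `TWO_STEP` a list with `step1` and `step2`.
#' @export
scenario_references <- function(scenario, validation_group, k = 5L) {
  v <- as.integer(validation_group)
  k <- as.integer(k)
  if (v < 1L || v > k) stop("validation_group must be in 1..", k)
  switch(scenario,
    S80 = cyc(v, seq_len(k - 1L), k),
    S60 = cyc(v, 1:3, k),
    S40 = cyc(v, 1:2, k),
    TWO_STEP = list(step1 = cyc(v, 1:2, k), step2 = cyc(v, -(2:1), k)),
    stop("unknown scenario: ", scenario)
  )
}

#' Full cross-validation plan for a scenario
#'
#' One fold per group, iterated in label order 1..k; each fold records its
#' validation group and reference groups (or the step-1/step-2 pair for the
#' two-step design).
#'
#' @param assignment a [assign_groups()] result.
#' @param scenario scenario name (see [scenario_references()]).
#' @return A `scenario_plan`: list with `scenario`, `assignment`, `folds`.
#' @export
scenario_plan <- function(assignment, scenario) {
  stopifnot(inherits(assignment, "group_assignment"))
  k <- assignment$k
  folds <- lapply(seq_len(k), function(v) {
    refs <- scenario_references(scenario, v, k)
    if (scenario == "TWO_STEP") {
      list(validation_group = v,
           step1_reference_groups = refs$step1,
           step2_reference_groups = refs$step2)
    } else {
      list(validation_group = v, reference_groups = refs)
    }
  })
  structure(list(scenario = scenario, assignment = assignment, folds = folds),
            class = "scenario_plan")
}

group_members <- function(assignment, groups) {
  which(assignment$group_of %in% groups)
}

#' Serialise a scenario plan to TSV
#'
#' One row per (fold, role, individual): columns `fold`, `role`
#' (`validation`, `reference`, `reference_step1`, `reference_step2`),
#' `group`, `individual_id`.
#'
#' @param plan a [scenario_plan()].
#' @param file output path.
#' @return the written data.frame, invisibly.
#' @export
write_plan_tsv <- function(plan, file) {
  asn <- plan$assignment
  rows <- list()
  for (f in plan$folds) {
    v <- f$validation_group
    add <- function(role, groups) {
      idx <- group_members(asn, groups)
      data.frame(fold = v, role = role, group = asn$group_of[idx],
                 individual_id = names(asn$group_of)[idx],
                 stringsAsFactors = FALSE)
    }
    rows[[length(rows) + 1L]] <- add("validation", v)
    if (plan$scenario == "TWO_STEP") {
      rows[[length(rows) + 1L]] <- add("reference_step1",
                                       f$step1_reference_groups)
      rows[[length(rows) + 1L]] <- add("reference_step2",
                                       f$step2_reference_groups)
    } else {
      rows[[length(rows) + 1L]] <- add("reference", f$reference_groups)
    }
  }
  out <- do.call(rbind, rows)
  utils::write.table(out, file, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(out)
}
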