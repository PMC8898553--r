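#' Enumerate the trial design of the single-condition tracking experiment
#'
#' From each 10 s scene, six trials are derived: one per combination of set
#' size (1, 3 or 5 targets) and query type (target queried vs. distractor
#' queried), so 23 scenes give 138 trials with exactly 50% target queries.
#' Target sets are drawn uniformly without replacement per trial; the
#' queried distractor is drawn uniformly among non-targets.
#'
#' @param videos Character vector of scene identifiers (23 in the study).
#' @param set_sizes Integer vector of tracking loads (default `c(1, 3, 5)`).
#' @param n_objects Objects available per scene, a single count or a named
#'   vector by scene (the aquarium scenes held 15-17 fish; default 16).
#' @param condition Condition label attached to every trial.
#' @param seed Integer seed controlling target/query draws.
#' @return A data frame of trial specifications: `trial_id`, `condition`,
#'   `stim_id`, `n_targets`, `target_ids` (semicolon-joined), `queried_id`,
#'   `queried_is_target`.
#' @export
#' @examples
#' d <- build_design_exp1(sprintf("v%02d", 1:23))
#' nrow(d)            # 138
#' mean(d$queried_is_target)  # 0.5
build_design_exp1 <- function(videos, set_sizes = c(1, 3, 5), n_objects = 16,
                              condition = "FISH", seed = 1) {
  build_design_grid(videos, set_sizes, n_objects, condition, seed,
                    stim_ids = videos)
}

#' Enumerate the trial design of the three-condition tracking experiment
#'
#' Each condition has 23 scenes x 2 loads (2 or 4 targets) x 2 query types
#' = 92 trials, loads uniformly balanced and target-query probability 50%.
#' The real-fish condition reuses the same video at both loads; the
#' circle-tracking conditions use trajectory sets unique to the condition.
#'
#' @inheritParams build_design_exp1
#' @param loads Tracking loads (default `c(2, 4)`).
#' @export
#' @examples
#' nrow(build_design_exp2(sprintf("v%02d", 1:23), condition = "FISH"))  # 92
build_design_exp2 <- function(videos, loads = c(2, 4), n_objects = 16,
                              condition = c("FISH", "FAKEFISH", "TRADITIONAL"),
                              seed = 1) {
  condition <- match.arg(condition)
  stim_ids <- if (condition == "FISH") videos
              else paste0(tolower(condition), "_", videos)
  build_design_grid(videos, loads, n_objects, condition, seed,
                    stim_ids = stim_ids)
}

# Shared enumerator: |videos| x |set_sizes| x {target, distractor} trials.
build_design_grid <- function(videos, set_sizes, n_objects, condition, seed,
                              stim_ids) {
  if (length(videos) < 1L || length(set_sizes) < 1L) {
    stop("invalid design: empty videos or set sizes", call. = FALSE)
  }
  n_obj <- if (length(n_objects) == 1L) {
    stats::setNames(rep(n_objects, length(videos)), videos)
  } else n_objects[videos]
  if (any(max(set_sizes) >= n_obj)) {
    stop("invalid design: set size must be below the object count",
         call. = FALSE)
  }
  with_seed(seed, {
    rows <- list()
    for (vi in seq_along(videos)) {
      v <- videos[vi]
      for (ss in set_sizes) {
        for (qt in c(TRUE, FALSE)) {
          objs <- seq_len(n_obj[[v]])
          targets <- sample(objs, ss)
          pool <- if (qt) targets else setdiff(objs, targets)
          queried <- pool[sample.int(length(pool), 1L)]
          rows[[length(rows) + 1L]] <- data.frame(
            condition = condition, stim_id = stim_ids[vi],
            n_targets = as.integer(ss),
            target_ids = paste(sort(targets), collapse = ";"),
            queried_id = as.integer(queried),
            queried_is_target = qt)
        }
      }
    }
    out <- do.call(rbind, rows)
    out <- cbind(trial_id = sprintf("%s_%03d", condition, seq_len(nrow(out))),
                 out)
    out
  })
}

#' Counterbalance condition-block orderings across participants
#'
#' All 3! = 6 orderings of the three condition blocks are used, assigned
#' round-robin, so ordering counts differ by at most one.
#'
#' @param conditions Character vector of condition labels (3 in the study).
#' @param n_participants Number of participants (>= 1).
#' @return A data frame `participant`, `ordering` (integer index), and
#'   `block1`, `block2`, ... columns giving each participant's block order.
#' @export
#' @examples
#' counterbalance_orders(c("FISH", "FAKEFISH", "TRADITIONAL"), 12)
counterbalance_orders <- function(conditions, n_participants) {
  if (n_participants < 1) stop("need n_participants >= 1", call. = FALSE)
  perms <- all_permutations(length(conditions))
  k <- nrow(perms)
  ord_idx <- ((seq_len(n_participants) - 1L) %% k) + 1L
  blocks <- matrix(conditions[t(perms[ord_idx, , drop = FALSE])],
                   nrow = n_participants, byrow = TRUE)
  colnames(blocks) <- paste0("block", seq_along(conditions))
  data.frame(participant = seq_len(n_participants), ordering = ord_idx,
             blocks, stringsAsFactors = FALSE)
}

# All permutations of 1..n in lexicographic order, one per row.
all_permutations <- function(n) {
  if (n == 1L) return(matrix(1L, 1, 1))
  sub <- all_permutations(n - 1L)
  out <- NULL
  for (first in seq_len(n)) {
    rest <- setdiff(seq_len(n), first)
    out <- rbind(out, cbind(first, matrix(rest[sub], nrow(sub))))
  }
  unname(out)
}

#' Shuffle a trial table for one participant
#'
#' Deterministic permutation of the trial rows given a participant seed.
#'
#' @param trials Trial data frame (as from the design builders).
#' @param participant_seed Integer seed.
#' @export
shuffle_trials <- function(trials, participant_seed) {
  with_seed(participant_seed, trials[sample(nrow(trials)), , drop = FALSE])
}

#' Read/write design CSV
#'
#' Columns `trial_id,condition,stim_id,n_targets,target_ids,queried_id,
#' queried_is_target`.
#' @param design Design data frame.
#' @param path CSV path.
#' @export
write_design <- function(design, path) {
  utils::write.csv(design, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_design
#' @export
read_design <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  df$queried_is_target <- as.logical(df$queried_is_target)
  df
}
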