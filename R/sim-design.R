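#' Simulate the cross-fostered experimental design
#'
#' Emulates the field protocol: clutches are alternately assigned to the
#' control or testosterone group; within each pair of broods (one clutch per
#' treatment) roughly half the nestlings are swapped between nests, so every
#' rearing brood contains nestlings of both treatments.  Brood sizes are
#' Poisson around `brood_size_mean`, truncated at 2 so a swap of at least one
#' nestling per direction is always possible; sexes are drawn independently
#' with probability `p_male`.
#'
#' @param config a [sim_config()] object.
#' @return a `data.frame` (class `sample_design`) with columns `individual`,
#'   `sex` (`"F"`/`"M"`), `treatment` (`"control"`/`"testosterone"`),
#'   `brood_origin`, `brood_rearing`.
#' @examples
#' d <- simulate_design(sim_config(seed = 1, n_brood_pairs = 2))
#' table(d$treatment, d$brood_rearing)
#' @export
simulate_design <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  with_child_seed(config, "design", {
    n_pairs <- config$n_brood_pairs
    n_broods <- 2L * n_pairs
    # clutches alternately assigned: odd broods control, even testosterone
    trt_of_brood <- rep(c("control", "testosterone"), n_pairs)
    brood_ids <- sprintf("brood%02d", seq_len(n_broods))
    # Poisson brood sizes truncated at >= 2
    lam <- config$brood_size_mean
    sizes <- qpois(runif(n_broods, ppois(1L, lam), 1), lam)

    rows <- vector("list", n_broods)
    ind_counter <- 0L
    for (pair in seq_len(n_pairs)) {
      a <- 2L * pair - 1L
      b <- 2L * pair
      for (side in c(a, b)) {
        other <- if (side == a) b else a
        sz <- sizes[side]
        n_swap <- max(1L, sz %/% 2L)  # about half leave for the partner nest
        rearing <- c(rep(brood_ids[other], n_swap),
                     rep(brood_ids[side], sz - n_swap))
        rows[[side]] <- data.frame(
          individual = sprintf("ind%04d", ind_counter + seq_len(sz)),
          sex = ifelse(runif(sz) < config$p_male, "M", "F"),
          treatment = trt_of_brood[side],
          brood_origin = brood_ids[side],
          brood_rearing = rearing,
          stringsAsFactors = FALSE)
        ind_counter <- ind_counter + sz
      }
    }
    design <- do.call(rbind, rows)
    rownames(design) <- NULL
    class(design) <- c("sample_design", "data.frame")
    design
  })
}

validate_design <- function(design) {
  need <- c("individual", "sex", "treatment", "brood_origin", "brood_rearing")
  if (!all(need %in% names(design)))
    stop("design must have columns: ", paste(need, collapse = ", "))
  if (anyDuplicated(design$individual))
    stop("duplicate individual ids in design")
  if (!all(design$treatment %in% c("control", "testosterone")))
    stop("treatment must be 'control' or 'testosterone'")
  if (!all(design$sex %in% c("F", "M")))
    stop("sex must be 'F' or 'M'")
  invisible(design)
}

#' Read / write a sample design table
#'
#' @param design a design `data.frame` as returned by [simulate_design()].
#' @param path CSV file path.
#' @return `read_design` returns the validated design; `write_design`
#'   (invisibly) the path.
#' @export
write_design <- function(design, path) {
  validate_design(design)
  utils::write.csv(design, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_design
#' @export
read_design <- function(path) {
  design <- utils::read.csv(path, stringsAsFactors = FALSE)
  validate_design(design)
  class(design) <- c("sample_design", "data.frame")
  design
}
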