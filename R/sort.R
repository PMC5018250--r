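#' Two-class sorting of segments by helical rise
#'
#' Separates a mixed segment stack into two classes differing in helical
#' symmetry (typically in axial rise). Cycle 0 builds a single reconstruction
#' from the unsorted set and symmetrizes it twice — once with each candidate
#' symmetry — to create two reference volumes. Each sorting cycle then
#' assigns every segment to the reference giving the higher best matching
#' correlation (ties go to class a, deterministically), rebuilds the two
#' class reconstructions from their members, and repeats.
#'
#' @param stack Mixed [segment_stack()].
#' @param sym_a,sym_b Candidate [helical_symmetry()] objects; must differ.
#' @param n_cycles Number of sorting cycles (default 5).
#' @param n_init_iter Alignment iterations for the unsorted seed
#'   reconstruction (default 2).
#' @param angular_step_deg,psi_grid_deg,shift_range_px Alignment settings,
#'   as in [ihrsr()].
#' @param refine_symmetry If TRUE, each class's symmetry is re-searched
#'   after every cycle; default FALSE (classes keep the candidate symmetry).
#' @param verbose Print per-cycle class counts.
#' @return Object of class `"sort_result"`: list with `labels` (1/2 per
#'   segment), `volume_a`, `volume_b`, `history` (per-cycle counts and, if
#'   true classes are known, accuracy), `accuracy` (NA when ground truth is
#'   absent), `n_cycles`.
#' @export
sort_segments <- function(stack, sym_a, sym_b, n_cycles = 5,
                          n_init_iter = 2, angular_step_deg = 4,
                          psi_grid_deg = c(-4, -2, 0, 2, 4),
                          shift_range_px = NULL,
                          refine_symmetry = FALSE, verbose = FALSE) {
  stopifnot(inherits(stack, "segment_stack"))
  if (isTRUE(all.equal(c(sym_a$twist_deg, sym_a$rise_A, sym_a$cyclic_order),
                       c(sym_b$twist_deg, sym_b$rise_A, sym_b$cyclic_order))))
    warning("sym_a equals sym_b; sorting cannot do better than chance")
  if (!isTRUE(stack$ctf_weighted) && !is.null(stack$meta$defocus_A))
    stack <- phase_flip(stack)
  vx <- stack$pixel_size_A
  if (is.null(shift_range_px))
    shift_range_px <- c(4, ceiling(max(sym_a$rise_A, sym_b$rise_A) / vx) + 3)
  sym_mid <- helical_symmetry((sym_a$twist_deg + sym_b$twist_deg) / 2,
                              (sym_a$rise_A + sym_b$rise_A) / 2,
                              sym_a$cyclic_order)
  seed_fit <- ihrsr(stack, sym_mid, max_iter = n_init_iter,
                    angular_step_deg = angular_step_deg,
                    psi_grid_deg = psi_grid_deg,
                    shift_range_px = shift_range_px,
                    search_symmetry = FALSE, auto_flip = FALSE)
  vol_a <- symmetrize(seed_fit$volume, sym_a)
  vol_b <- symmetrize(seed_fit$volume, sym_b)
  truth <- stack$meta$class
  have_truth <- !is.null(truth) && length(unique(truth)) == 2
  hist <- data.frame()
  labels <- NULL
  for (cy in seq_len(n_cycles)) {
    ref_a <- make_references(vol_a, sym_a, angular_step_deg)
    ref_b <- make_references(vol_b, sym_b, angular_step_deg)
    par_a <- align_segments(stack, ref_a, shift_range_px, psi_grid_deg)
    par_b <- align_segments(stack, ref_b, shift_range_px, psi_grid_deg)
    labels <- ifelse(par_a$score >= par_b$score, 1L, 2L)  # ties -> class a
    n_a <- sum(labels == 1L)
    n_b <- sum(labels == 2L)
    if (n_a == 0 || n_b == 0)
      stop(sprintf("class %s emptied at sorting cycle %d",
                   if (n_a == 0) "a" else "b", cy))
    acc <- if (have_truth) {
      raw <- mean(labels == truth)
      max(raw, 1 - raw)    # class naming is arbitrary
    } else NA_real_
    hist <- rbind(hist, data.frame(cycle = cy, n_a = n_a, n_b = n_b,
                                   accuracy = acc))
    if (verbose)
      message(sprintf("cycle %d: %d / %d segments%s", cy, n_a, n_b,
                      if (have_truth) sprintf(", accuracy %.1f%%", 100 * acc)
                      else ""))
    idx_a <- which(labels == 1L)
    idx_b <- which(labels == 2L)
    vol_a <- symmetrize(backproject(stack[idx_a], par_a[idx_a, ]), sym_a)
    vol_b <- symmetrize(backproject(stack[idx_b], par_b[idx_b, ]), sym_b)
    if (refine_symmetry) {
      sym_a <- symmetry_search(vol_a, sym_a)
      sym_b <- symmetry_search(vol_b, sym_b)
    }
  }
  structure(list(labels = labels, volume_a = vol_a, volume_b = vol_b,
                 sym_a = sym_a, sym_b = sym_b, history = hist,
                 accuracy = hist$accuracy[nrow(hist)], n_cycles = n_cycles),
            class = "sort_result")
}

#' @export
print.sort_result <- function(x, ...) {
  cat("Two-class rise sorting\n")
  h <- x$history[nrow(x$history), ]
  cat(sprintf("  %d cycles, final classes: %d / %d\n", x$n_cycles,
              h$n_a, h$n_b))
  if (!is.na(x$accuracy))
    cat(sprintf("  accuracy vs ground truth: %.1f%%\n", 100 * x$accuracy))
  invisible(x)
}

#' Confusion matrix of a sorting result against ground-truth labels
#'
#' @param result A [sort_segments()] result.
#' @param truth True class labels (1/2); defaults to the stack metadata the
#'   result was computed from if stored.
#' @return 2x2 table (assigned x truth).
#' @export
sorting_confusion <- function(result, truth) {
  table(assigned = result$labels, truth = truth)
}
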