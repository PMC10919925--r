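# Recovery scoring: compare pipeline output against the generator's truth
# tables.

# expected retention fraction given per-copy loss probabilities, with
# both-copies-lost OGs excluded from the denominator
.expected_retention <- function(loss_self, loss_other) {
  (1 - loss_self) / (1 - loss_self * loss_other)
}

#' Score pipeline output against simulation truth
#'
#' Computes, per cross: donor-inference correctness; quartet-detector
#' false-positive rate, direction accuracy among directional calls, and
#' recall of injected conversions; site-detector precision and recall
#' (matching on clade, gene, column and direction); retention-bias
#' estimation error against the analytically expected bias; and
#' expression-bias class accuracy among expressed pairs.
#'
#' @param sim the [simulate_triangle()] dataset (carries `truth`).
#' @param report the [run_pipeline()] result for that dataset.
#' @return Nested list of recovery metrics, with an `overall` element
#'   pooling both crosses.
#' @export
evaluate_recovery <- function(sim, report) {
  truth <- sim$truth
  crosses <- names(sim$designs)
  out <- list()

  for (cross in crosses) {
    res <- list()

    if (!is.null(report$typing)) {
      donor <- report$typing[[cross]]$donor
      res$donor <- list(
        inferred = donor$genome_id,
        expected = unname(truth$donor[[cross]]),
        correct = identical(donor$genome_id, unname(truth$donor[[cross]])) &&
          donor$status == "confident",
        support = donor$support)
    }

    if (!is.null(report$quartet)) {
      tq <- truth$quartet
      tq <- tq[tq$cross == cross & tq$both_retained, , drop = FALSE]
      calls <- report$quartet[[cross]]$calls
      m <- merge(calls, tq[, c("og_id", "converted", "direction")],
                 by = "og_id")
      if (any(!calls$og_id %in% tq$og_id)) {
        stop("quartet calls reference OGs missing from truth")
      }
      directional <- m$call %in% c("P_to_M", "M_to_P")
      n_null <- sum(!m$converted)
      fp <- sum(directional & !m$converted)
      conv <- m$converted
      correct_dir <- directional & conv & m$call == m$direction
      res$quartet <- list(
        n_ogs = nrow(m),
        n_converted = sum(conv),
        n_null = n_null,
        n_false_positive = fp,
        n_directional_on_converted = sum(directional & conv),
        n_correct_direction = sum(correct_dir),
        false_positive_rate = if (n_null > 0) fp / n_null else NA_real_,
        direction_accuracy = if (sum(directional & conv) > 0) {
          sum(correct_dir) / sum(directional & conv)
        } else {
          NA_real_
        },
        recall = if (sum(conv) > 0) sum(correct_dir) / sum(conv) else NA_real_)
    }

    if (!is.null(report$sites)) {
      ts <- truth$sites
      ts <- ts[ts$cross == cross, , drop = FALSE]
      ev <- report$sites[[cross]]$events
      key <- function(d) paste(d$clade_id, d$gene_id, d$column, d$direction)
      detected <- key(ev)
      expected <- key(ts)
      res$sites <- list(
        n_truth = nrow(ts),
        n_detected = nrow(ev),
        precision = if (nrow(ev) > 0) mean(detected %in% expected) else NA_real_,
        recall = if (nrow(ts) > 0) mean(expected %in% detected) else NA_real_)
    }

    if (!is.null(report$retention)) {
      ret <- report$retention[[cross]]
      lp <- sim$config$loss_prob
      ret$expected_bias <- vapply(ret$category, function(cat) {
        .expected_retention(lp[cat, "maternal"], lp[cat, "paternal"]) -
          .expected_retention(lp[cat, "paternal"], lp[cat, "maternal"])
      }, numeric(1))
      den_m <- ifelse(ret$r_m > 0, ret$retained_maternal / ret$r_m, 0)
      den_p <- ifelse(ret$r_p > 0, ret$retained_paternal / ret$r_p, 0)
      ret$bias_se <- sqrt(
        ifelse(den_m > 0, ret$r_m * (1 - ret$r_m) / den_m, NA_real_) +
          ifelse(den_p > 0, ret$r_p * (1 - ret$r_p) / den_p, NA_real_))
      ret$bias_error <- ret$bias - ret$expected_bias
      res$retention <- ret
    }

    if (!is.null(report$expression)) {
      te <- truth$expression
      te <- te[te$cross == cross, , drop = FALSE]
      recs <- report$expression[[cross]]$records
      m <- merge(recs, te, by = "og_id")
      expressed <- m$bias_class != "not_expressed"
      res$expression <- list(
        n_pairs = nrow(m),
        class_accuracy = if (any(expressed)) {
          mean(m$bias_class[expressed] == m$class[expressed])
        } else {
          NA_real_
        })
    }
    out[[cross]] <- res
  }

  overall <- list()
  if (!is.null(report$quartet)) {
    n_dir <- sum(vapply(crosses, function(cr) {
      out[[cr]]$quartet$n_directional_on_converted
    }, numeric(1)))
    n_corr <- sum(vapply(crosses, function(cr) {
      out[[cr]]$quartet$n_correct_direction
    }, numeric(1)))
    n_fp <- sum(vapply(crosses, function(cr) out[[cr]]$quartet$n_false_positive,
                       numeric(1)))
    n_null <- sum(vapply(crosses, function(cr) out[[cr]]$quartet$n_null,
                         numeric(1)))
    n_conv <- sum(vapply(crosses, function(cr) out[[cr]]$quartet$n_converted,
                         numeric(1)))
    overall$quartet_direction_accuracy <- if (n_dir > 0) n_corr / n_dir else NA_real_
    overall$quartet_false_positive_rate <- if (n_null > 0) n_fp / n_null else NA_real_
    overall$quartet_recall <- if (n_conv > 0) n_corr / n_conv else NA_real_
  }
  if (!is.null(report$sites)) {
    n_det <- sum(vapply(crosses, function(cr) out[[cr]]$sites$n_detected, numeric(1)))
    n_tru <- sum(vapply(crosses, function(cr) out[[cr]]$sites$n_truth, numeric(1)))
    hits <- sum(vapply(crosses, function(cr) {
      out[[cr]]$sites$recall * out[[cr]]$sites$n_truth
    }, numeric(1)))
    tp_det <- sum(vapply(crosses, function(cr) {
      out[[cr]]$sites$precision * out[[cr]]$sites$n_detected
    }, numeric(1)))
    overall$site_precision <- if (n_det > 0) tp_det / n_det else NA_real_
    overall$site_recall <- if (n_tru > 0) hits / n_tru else NA_real_
  }
  if (!is.null(report$typing)) {
    overall$donor_all_correct <- all(vapply(crosses, function(cr) {
      isTRUE(out[[cr]]$donor$correct)
    }, logical(1)))
  }
  out$overall <- overall
  out
}
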