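# Entry-point planner: fixed amygdala-derived target, candidate entries on
# prioritized entry gyri, feasibility filtering (ventricle exclusion, safety
# margin, drilling angle) and weighted ranking.

#' Planner configuration
#'
#' @param target_offset Displacement of the amygdala centroid in
#'   (medial, anterior, inferior) mm; default `c(3, 3, 3)`.
#' @param entry_roles Entry gyri in priority order.
#' @param entry_spacing World-space pitch between candidate entry points on
#'   the patch surface, mm.
#' @param max_drilling_angle Maximum allowed drilling angle, degrees.
#' @param enforce_safety_margin Apply the critical-structure clearance
#'   filter.
#' @param weights Named or positional numeric vector
#'   (`w_risk`, `w_ahc`, `w_len`, `w_angle`), all >= 0.
#' @param risk_params A [risk_params].
#' @return Object of class `plan_config`.
#' @export
plan_config <- function(target_offset = c(3, 3, 3),
                        entry_roles = c("entry_inferior_occipital",
                                        "entry_middle_occipital",
                                        "entry_posterior_middle_temporal"),
                        entry_spacing = 2.0,
                        max_drilling_angle = 45,
                        enforce_safety_margin = TRUE,
                        weights = c(w_risk = 1, w_ahc = 1,
                                    w_len = 0.25, w_angle = 0.25),
                        risk_params = littplan::risk_params()) {
  stopifnot(length(entry_roles) >= 1, entry_spacing > 0,
            all(weights >= 0), length(weights) == 4)
  if (is.null(names(weights)))
    names(weights) <- c("w_risk", "w_ahc", "w_len", "w_angle")
  structure(list(target_offset = target_offset, entry_roles = entry_roles,
                 entry_spacing = entry_spacing,
                 max_drilling_angle = max_drilling_angle,
                 enforce_safety_margin = enforce_safety_margin,
                 weights = weights, risk_params = risk_params),
            class = "plan_config")
}

#' Planning target from the amygdala
#'
#' Centroid of the amygdala voxel centers displaced medially (toward the
#' midline: +x for a left-sided, -x for a right-sided amygdala in RAS),
#' anteriorly (+y) and inferiorly (-z) by the offset components.
#'
#' @param amygdala Amygdala [roi_mask], non-empty.
#' @param volume The parent [label_volume].
#' @param side `"left"` or `"right"`.
#' @param offset `(medial, anterior, inferior)` mm.
#' @return World point (length-3 numeric).
#' @export
make_target <- function(amygdala, volume, side = c("left", "right"),
                        offset = c(3, 3, 3)) {
  side <- match.arg(side)
  if (!any(amygdala$mask)) stop("amygdala mask is empty")
  ctr <- colMeans(mask_world_coords(amygdala$mask, volume$affine))
  medial_sign <- if (side == "left") 1 else -1
  ctr + c(medial_sign * offset[1], offset[2], -offset[3])
}

#' Candidate entry points on an entry-gyrus patch
#'
#' Surface voxels of the patch (a face neighbor outside the intracranial
#' mask), subsampled on a world-space grid of pitch `spacing` and ordered
#' lexicographically by world (z, y, x) for reproducibility.
#'
#' @param entry_patch Patch [roi_mask].
#' @param brain Logical intracranial mask (see [intracranial_mask]).
#' @param volume The parent [label_volume].
#' @param spacing Subsampling pitch, mm.
#' @return Matrix of world points (rows); zero rows (with a warning) for an
#'   empty patch.
#' @export
candidate_entries <- function(entry_patch, brain, volume, spacing = 2.0) {
  if (!any(entry_patch$mask)) {
    warning("entry patch is empty: ", entry_patch$role)
    return(matrix(numeric(0), ncol = 3))
  }
  m <- entry_patch$mask
  dm <- dim(m)
  outside <- !brain
  surf <- array(FALSE, dm)
  # face-neighbor shifts; out-of-grid neighbors count as outside
  shift_out <- function(axis, dir) {
    o <- array(TRUE, dm)
    idx_src <- lapply(dm, seq_len)
    idx_dst <- idx_src
    n <- dm[axis]
    if (dir > 0) { idx_dst[[axis]] <- 1:(n - 1); idx_src[[axis]] <- 2:n }
    else { idx_dst[[axis]] <- 2:n; idx_src[[axis]] <- 1:(n - 1) }
    o <- array(TRUE, dm)
    o[idx_dst[[1]], idx_dst[[2]], idx_dst[[3]]] <-
      outside[idx_src[[1]], idx_src[[2]], idx_src[[3]]]
    o
  }
  for (axis in 1:3) for (dir in c(-1, 1))
    surf <- surf | (m & shift_out(axis, dir))
  pts <- mask_world_coords(surf, volume$affine)
  if (nrow(pts) == 0) {
    warning("entry patch has no surface voxels: ", entry_patch$role)
    return(matrix(numeric(0), ncol = 3))
  }
  ord <- order(pts[, 3], pts[, 2], pts[, 1])
  pts <- pts[ord, , drop = FALSE]
  bin <- paste(floor(pts[, 1] / spacing), floor(pts[, 2] / spacing),
               floor(pts[, 3] / spacing))
  pts <- pts[!duplicated(bin), , drop = FALSE]
  ord <- order(pts[, 3], pts[, 2], pts[, 1])
  pts[ord, , drop = FALSE]
}

#' Feasibility of a trajectory
#'
#' Checks, in order: ventricular transgression (the ventricles are an
#' exclusion zone), the critical-structure safety margin, and the maximum
#' drilling angle. The first failing check is reported.
#'
#' @param traj A [trajectory].
#' @param bundle An [anatomy_bundle].
#' @param config A [plan_config].
#' @param metrics Optional precomputed [compute_metrics] result.
#' @return List with `ok` (logical), `reason` (`""`, `"ventricle"`,
#'   `"safety_margin"`, `"drilling_angle"` or `"metric_error"`) and
#'   `metrics`.
#' @export
feasible <- function(traj, bundle, config = plan_config(),
                     metrics = NULL) {
  m <- if (is.null(metrics)) {
    tryCatch(compute_metrics(traj, bundle, config$risk_params),
             error = function(e) NULL)
  } else metrics
  needed <- c("min_critical_distance", "drilling_angle")
  if (is.null(m) || any(is.na(unlist(m[needed]))) ||
      "ventricle_hit" %in% names(m$errors))
    return(list(ok = FALSE, reason = "metric_error", metrics = m))
  if (isTRUE(m$ventricle_hit))
    return(list(ok = FALSE, reason = "ventricle", metrics = m))
  if (config$enforce_safety_margin &&
      m$min_critical_distance < config$risk_params$safety_margin)
    return(list(ok = FALSE, reason = "safety_margin", metrics = m))
  if (m$drilling_angle > config$max_drilling_angle)
    return(list(ok = FALSE, reason = "drilling_angle", metrics = m))
  list(ok = TRUE, reason = "", metrics = m)
}

#' Trajectory ranking score (lower is better)
#'
#' `w_risk * overall_risk - w_ahc * ahc_center_proportion +
#'  w_len * length/150 + w_angle * angle/90`; the normalizers place length
#' and angle on roughly `[0, 1]`, comparable to the risk and AHC terms.
#'
#' @param metrics A [compute_metrics] result.
#' @param config A [plan_config].
#' @return Numeric score.
#' @export
trajectory_score <- function(metrics, config = plan_config()) {
  w <- config$weights
  unname(w[1] * metrics$overall_risk -
           w[2] * metrics$ahc_center_proportion +
           w[3] * metrics$intracerebral_length / 150 +
           w[4] * metrics$drilling_angle / 90)
}

#' Plan the optimal LiTT trajectory
#'
#' Fixes the target from the amygdala, then walks the entry gyri in
#' priority order: all candidate entries of a role are evaluated against
#' the target; if at least one is feasible the minimum-score feasible
#' candidate is returned (ties broken by lower risk, then shorter length,
#' then candidate order) and later roles are not evaluated. When no role
#' yields a feasible candidate an infeasible result carrying the rejection
#' tally is returned.
#'
#' @param bundle An [anatomy_bundle].
#' @param config A [plan_config].
#' @param top_k Number of ranked alternatives to retain.
#' @return Object of class `plan_result`: `feasible`, `trajectory`,
#'   `metrics`, `entry_role_used`, `score`, `target`,
#'   `n_candidates_evaluated`, `n_feasible`, `rejection_tally`,
#'   `ranked_alternatives`.
#' @export
plan_trajectory <- function(bundle, config = plan_config(), top_k = 5) {
  target <- make_target(bundle$amygdala, bundle$volume, bundle$side,
                        config$target_offset)
  brain <- intracranial_mask(bundle$volume)
  tally <- c(ventricle = 0L, safety_margin = 0L, drilling_angle = 0L,
             metric_error = 0L)
  n_eval <- 0L
  for (role in config$entry_roles) {
    patch <- extract_roi(bundle$volume, role)
    cands <- suppressWarnings(
      candidate_entries(patch, brain, bundle$volume,
                        config$entry_spacing))
    if (nrow(cands) == 0) next
    rows <- vector("list", nrow(cands))
    for (i in seq_len(nrow(cands))) {
      traj <- trajectory(cands[i, ], target, label = "cap")
      fz <- feasible(traj, bundle, config)
      n_eval <- n_eval + 1L
      if (!fz$ok) {
        tally[fz$reason] <- tally[fz$reason] + 1L
        next
      }
      rows[[i]] <- list(traj = traj, metrics = fz$metrics,
                        score = trajectory_score(fz$metrics, config),
                        index = i)
    }
    rows <- Filter(Negate(is.null), rows)
    if (length(rows) > 0) {
      score <- vapply(rows, `[[`, 0, "score")
      risk <- vapply(rows, function(r) r$metrics$overall_risk, 0)
      len <- vapply(rows, function(r) r$metrics$intracerebral_length, 0)
      idx <- vapply(rows, `[[`, 0L, "index")
      ord <- order(score, risk, len, idx)
      best <- rows[[ord[1]]]
      alts <- lapply(head(ord, top_k), function(j)
        list(trajectory = rows[[j]]$traj, score = rows[[j]]$score,
             metrics = rows[[j]]$metrics))
      return(structure(list(
        feasible = TRUE, trajectory = best$traj, metrics = best$metrics,
        entry_role_used = role, score = best$score, target = target,
        n_candidates_evaluated = n_eval, n_feasible = length(rows),
        rejection_tally = tally, ranked_alternatives = alts),
        class = "plan_result"))
    }
  }
  structure(list(feasible = FALSE, trajectory = NULL, metrics = NULL,
                 entry_role_used = NA_character_, score = NA_real_,
                 target = target, n_candidates_evaluated = n_eval,
                 n_feasible = 0L, rejection_tally = tally,
                 ranked_alternatives = list()),
            class = "plan_result")
}

#' @export
print.plan_result <- function(x, ...) {
  if (x$feasible) {
    cat("feasible plan via", x$entry_role_used,
        sprintf("(score %.4f, %d/%d candidates feasible)\n",
                x$score, x$n_feasible, x$n_candidates_evaluated))
    print(x$trajectory)
    print(x$metrics)
  } else {
    cat("no feasible trajectory;", x$n_candidates_evaluated,
        "candidates evaluated\n")
    print(x$rejection_tally)
  }
  invisible(x)
}
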