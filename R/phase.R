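#' Wrapped phase from an N-step fringe stack
#'
#' The standard N-step least-squares estimator: with shift offsets
#' `delta_k = 2 pi k / N`,
#' `phi = atan2(-sum I_k sin delta_k, sum I_k cos delta_k)` in `(-pi, pi]`,
#' modulation estimate `B = (2/N) sqrt(S^2 + C^2)` and mean `A = mean(I_k)`.
#' Pixels are valid where the relative modulation `B/A` reaches
#' `quality_threshold` *and* the absolute modulation reaches
#' `min_modulation`: dark graphite markers scale A and B together, so only
#' an absolute floor can reject them, while the relative test rejects
#' grazing-incidence and saturated regions.
#'
#' @param stack a [render_fringe_stack()] result (or one read from disk).
#' @param quality_threshold minimum `B/A` for a valid pixel.
#' @param min_modulation minimum absolute modulation (intensity units).
#' @return a `wrapped_phase_map` with matrices `phase`, `modulation`,
#'   `mean_intensity` and `valid_mask`.
#' @export
wrapped_phase <- function(stack, quality_threshold = 0.1,
                          min_modulation = 10) {
  stopifnot(inherits(stack, "fringe_stack"))
  N <- length(stack$images)
  if (N < 3L) stop("need at least 3 phase-shifted frames", call. = FALSE)
  dims <- lapply(stack$images, dim)
  if (length(unique(dims)) != 1L) {
    stop("frames differ in size", call. = FALSE)
  }
  del <- stack$phase_offsets
  S <- C <- A <- 0
  for (k in seq_len(N)) {
    S <- S + stack$images[[k]] * sin(del[k])
    C <- C + stack$images[[k]] * cos(del[k])
    A <- A + stack$images[[k]]
  }
  A <- A / N
  B <- (2 / N) * sqrt(S^2 + C^2)
  phi <- atan2(-S, C)
  phi[phi <= -pi] <- pi  # canonical range (-pi, pi]
  valid <- (B >= min_modulation) & (A > 0) & (B / pmax(A, 1e-12) >= quality_threshold)
  structure(list(phase = phi, modulation = B, mean_intensity = A,
                 valid_mask = valid, frequency_id = stack$frequency_id,
                 rig = stack$rig),
            class = "wrapped_phase_map")
}

wrap_to_pi <- function(x) {
  w <- x - 2 * pi * round(x / (2 * pi))
  w[w <= -pi] <- pi
  w
}

#' Unwrap a wrapped phase map
#'
#' Temporal (default): a coarse one-stripe map `low` pins the fringe order
#' of the fine map via `k = round((ratio * phi_low - phi_high) / 2 pi)`,
#' `Phi = phi_high + 2 pi k` — absolute phase per pixel, no spatial error
#' propagation. Spatial: quality-guided flood fill from the
#' highest-modulation valid pixel, each new pixel unwrapped against its
#' already-unwrapped neighbour; the global 2-pi offset is anchored to the
#' temporal/low estimate at the seed pixel when a low map is supplied,
#' otherwise left at the seed's wrapped value. Disconnected valid regions
#' are unwrapped per region and flagged with a warning attribute.
#'
#' @param high `wrapped_phase_map` of the high (fine) frequency.
#' @param low `wrapped_phase_map` of the low frequency, or `NULL`
#'   (spatial only).
#' @param rig the rig configuration (supplies `frequency_ratio`).
#' @param method `"temporal"` or `"spatial"`.
#' @return an `unwrapped_phase_map` with `phase`, `valid_mask`, `method`.
#' @export
unwrap_phase <- function(high, low = NULL, rig = high$rig,
                         method = c("temporal", "spatial")) {
  method <- match.arg(method)
  stopifnot(inherits(high, "wrapped_phase_map"))
  if (!any(high$valid_mask)) stop("no valid pixels to unwrap", call. = FALSE)
  if (method == "temporal") {
    if (is.null(low)) {
      stop("temporal unwrapping requires a low-frequency map", call. = FALSE)
    }
    ratio <- rig$frequency_ratio
    low_abs <- absolute_low_phase(low, rig)
    k <- round((ratio * low_abs - high$phase) / (2 * pi))
    phase <- high$phase + 2 * pi * k
    valid <- high$valid_mask & low$valid_mask
    regions <- NULL
  } else {
    sp <- spatial_unwrap(high$phase, high$valid_mask, high$modulation)
    phase <- sp$phase
    valid <- high$valid_mask
    regions <- sp$n_regions
    # anchor the global offset to the absolute low-frequency estimate
    if (!is.null(low)) {
      seed <- sp$seed_index
      ratio <- rig$frequency_ratio
      low_abs <- absolute_low_phase(low, rig)
      target <- high$phase[seed] +
        2 * pi * round((ratio * low_abs[seed] - high$phase[seed]) / (2 * pi))
      phase <- phase + 2 * pi * round((target - phase[seed]) / (2 * pi))
    }
  }
  out <- structure(list(phase = phase, valid_mask = valid, method = method,
                        frequency_id = high$frequency_id, rig = rig),
                   class = "unwrapped_phase_map")
  if (!is.null(regions) && regions > 1L) {
    attr(out, "disconnected_regions") <- regions
    warning(regions, " disconnected valid regions unwrapped independently",
            call. = FALSE)
  }
  out
}

# Absolute phase of the low (one-stripe) map. The low pattern spans about
# one 2-pi period across the field, so its wrapped value is branch-ambiguous
# exactly at the field edges; height-induced deviations from the analytic
# reference-plane low phase are far below pi for in-range surfaces, so the
# branch is pinned to the reference.
absolute_low_phase <- function(low, rig) {
  ref_low <- reference_phase(rig, "low")
  low$phase + 2 * pi * round((ref_low - low$phase) / (2 * pi))
}

# quality-guided flood fill. Processes valid pixels in order of a
# modulation-keyed binary max-heap seeded at the best pixel of each
# connected region; neighbours (4-connectivity) are unwrapped against the
# pixel that enqueued them.
spatial_unwrap <- function(phi, valid, quality) {
  H <- nrow(phi); W <- ncol(phi)
  n <- H * W
  phase <- phi
  state <- integer(n)          # 0 untouched, 1 queued, 2 done
  state[!valid] <- 2L
  heap_idx <- integer(n); heap_key <- numeric(n); heap_n <- 0L
  push <- function(i, key) {
    heap_n <<- heap_n + 1L
    j <- heap_n
    heap_idx[j] <<- i; heap_key[j] <<- key
    while (j > 1L) {
      p <- j %/% 2L
      if (heap_key[p] >= heap_key[j]) break
      tmpi <- heap_idx[p]; heap_idx[p] <<- heap_idx[j]; heap_idx[j] <<- tmpi
      tmpk <- heap_key[p]; heap_key[p] <<- heap_key[j]; heap_key[j] <<- tmpk
      j <- p
    }
  }
  pop <- function() {
    top <- heap_idx[1L]
    heap_idx[1L] <<- heap_idx[heap_n]; heap_key[1L] <<- heap_key[heap_n]
    heap_n <<- heap_n - 1L
    j <- 1L
    while (TRUE) {
      l <- 2L * j; r <- l + 1L
      big <- j
      if (l <= heap_n && heap_key[l] > heap_key[big]) big <- l
      if (r <= heap_n && heap_key[r] > heap_key[big]) big <- r
      if (big == j) break
      tmpi <- heap_idx[big]; heap_idx[big] <<- heap_idx[j]; heap_idx[j] <<- tmpi
      tmpk <- heap_key[big]; heap_key[big] <<- heap_key[j]; heap_key[j] <<- tmpk
      j <- big
    }
    top
  }
  neighbours <- function(i) {
    r <- ((i - 1L) %% H) + 1L
    c <- ((i - 1L) %/% H) + 1L
    out <- integer(0)
    if (r > 1L) out <- c(out, i - 1L)
    if (r < H)  out <- c(out, i + 1L)
    if (c > 1L) out <- c(out, i - H)
    if (c < W)  out <- c(out, i + H)
    out
  }
  remaining <- which(valid)
  n_regions <- 0L
  seed_index <- NA_integer_
  while (length(remaining) > 0L) {
    seed <- remaining[which.max(quality[remaining])]
    if (n_regions == 0L) seed_index <- seed
    n_regions <- n_regions + 1L
    state[seed] <- 2L
    for (nb in neighbours(seed)) if (state[nb] == 0L) {
      state[nb] <- 1L
      phase[nb] <- phase[seed] + wrap_to_pi(phi[nb] - phase[seed])
      push(nb, quality[nb])
    }
    while (heap_n > 0L) {
      i <- pop()
      if (state[i] == 2L) next
      state[i] <- 2L
      for (nb in neighbours(i)) if (state[nb] == 0L) {
        state[nb] <- 1L
        phase[nb] <- phase[i] + wrap_to_pi(phi[nb] - phase[i])
        push(nb, quality[nb])
      }
    }
    remaining <- remaining[state[remaining] != 2L]
  }
  list(phase = phase, n_regions = n_regions, seed_index = seed_index)
}
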