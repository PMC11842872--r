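#' Contact map container
#'
#' Square symmetric matrix of contact probabilities between beads of a
#' simulated chromosome, with its genomic resolution.
#'
#' @param mat Square numeric matrix.
#' @param resolution_kb kb per bin.
#' @param normalization `"raw"` or `"oe"` (observed/expected).
#' @return Object of class `contact_map`.
#' @export
contact_map <- function(mat, resolution_kb, normalization = "raw") {
  mat <- as.matrix(mat)
  stopifnot(nrow(mat) == ncol(mat), all(is.finite(mat)), all(mat >= 0))
  structure(list(mat = mat, resolution_kb = resolution_kb,
                 normalization = normalization),
            class = "contact_map")
}

#' @export
print.contact_map <- function(x, ...) {
  cat(sprintf("Contact map: %d x %d bins at %g kb (%s)\n",
              nrow(x$mat), ncol(x$mat), x$resolution_kb, x$normalization))
  invisible(x)
}

#' Contact map from a loop-extrusion trajectory (effective-contour model)
#'
#' Desk-scale surrogate for 3D polymer dynamics: in each sampled
#' configuration, every extruder bridges its two legs, shortening the
#' effective contour between loci. The effective separation `d_eff(i, j)` is
#' the shortest-path distance on the bead graph with unit backbone edges
#' plus a unit shortcut edge across each loop, and the contact probability
#' follows the equilibrium-coil power law
#' \eqn{P_{ij} \propto \max(d_{eff}, 1)^{exponent}} (exponent -1.5 for a
#' theta-solvent random walk). Maps are averaged over samples and
#' symmetric by construction.
#'
#' @param traj A [run_extrusion()] trajectory (may contain samples with zero
#'   extruders; an empty trajectory is an error).
#' @param exponent Contact-decay exponent (default -1.5).
#' @return A [contact_map()] at the trajectory's resolution.
#' @export
contacts_from_loops <- function(traj, exponent = -1.5) {
  stopifnot(inherits(traj, "lattice_trajectory"))
  if (length(traj$samples) == 0) stop("empty trajectory")
  n <- traj$params$chain_length
  backbone <- cbind(seq_len(n - 1L), 2:n)
  acc <- matrix(0, n, n)
  for (s in traj$samples) {
    edges <- backbone
    if (nrow(s) > 0) edges <- rbind(edges, cbind(s$left, s$right))
    g <- igraph::graph_from_edgelist(edges, directed = FALSE)
    d <- igraph::distances(g)                       # unweighted: BFS
    acc <- acc + pmax(d, 1)^exponent
  }
  contact_map(acc / length(traj$samples), traj$params$resolution_kb)
}

# brute-force reference used in tests: Floyd-Warshall effective separation
# for a single configuration (small chains only)
dense_shortest_paths <- function(n, loops) {
  d <- abs(outer(seq_len(n), seq_len(n), "-"))
  if (nrow(loops) > 0) {
    for (i in seq_len(nrow(loops))) {
      d[loops$left[i], loops$right[i]] <- 1
      d[loops$right[i], loops$left[i]] <- 1
    }
    for (k in seq_len(n)) {
      d <- pmin(d, outer(d[, k], d[k, ], "+"))
    }
  }
  d
}

#' Average contact probability P(s)
#'
#' Mean contact probability over all locus pairs at each genomic separation,
#' optionally log-binned, with the local log-log slope estimated by centered
#' finite differences after moving-average smoothing.
#'
#' @param map A [contact_map()].
#' @param bins_per_decade Log-bins per decade of separation; `NULL` (default)
#'   keeps every separation unbinned.
#' @param smooth Moving-average window (odd, in curve points) applied to
#'   log P before the slope; 1 disables smoothing.
#' @return Object of class `ps_curve`: data frame with `s_kb`, `p`, `slope`.
#' @export
ps_curve <- function(map, bins_per_decade = NULL, smooth = 3L) {
  stopifnot(inherits(map, "contact_map"))
  m <- map$mat
  n <- nrow(m)
  s <- seq_len(n - 1L)
  p <- vapply(s, function(k) {
    i <- seq_len(n - k)
    mean(m[cbind(i, i + k)])
  }, numeric(1))
  if (!is.null(bins_per_decade)) {
    bin <- floor(log10(s) * bins_per_decade)
    p <- tapply(p, bin, mean)
    s <- tapply(s, bin, function(x) exp(mean(log(x))))
  }
  keep <- p > 0
  s <- s[keep]; p <- p[keep]
  lp <- log(p); ls <- log(s)
  if (smooth > 1 && length(lp) >= smooth) {
    sm <- stats::filter(lp, rep(1 / smooth, smooth), sides = 2)
    lp_s <- ifelse(is.na(sm), lp, as.numeric(sm))
  } else lp_s <- lp
  k <- length(lp_s)
  slope <- rep(NA_real_, k)
  if (k >= 3) {
    slope[2:(k - 1)] <- (lp_s[3:k] - lp_s[1:(k - 2)]) /
      (ls[3:k] - ls[1:(k - 2)])
  }
  structure(data.frame(s_kb = s * map$resolution_kb, p = as.numeric(p),
                       slope = slope),
            class = c("ps_curve", "data.frame"))
}

#' Fit the log-log slope of P(s) over a separation range
#'
#' Ordinary least squares of `log P` on `log s` restricted to
#' `[s_min_kb, s_max_kb]`.
#'
#' @param curve A [ps_curve()].
#' @param s_min_kb,s_max_kb Separation range (kb).
#' @return Fitted slope.
#' @export
ps_slope_fit <- function(curve, s_min_kb, s_max_kb) {
  sub <- curve[curve$s_kb >= s_min_kb & curve$s_kb <= s_max_kb & curve$p > 0, ]
  if (nrow(sub) < 2) stop("fewer than 2 points in the fit range")
  unname(stats::coef(stats::lm(log(p) ~ log(s_kb), data = sub))[2])
}

#' Ratio of P(s) slopes between two conditions
#'
#' Elementwise ratio `slope_a / slope_b` on the separations common to both
#' curves; entries where the denominator slope is (near) zero are masked
#' with `NA`.
#'
#' @param curve_a,curve_b [ps_curve()] objects.
#' @param eps Mask threshold for the denominator.
#' @return Data frame with `s_kb`, `slope_a`, `slope_b`, `ratio`.
#' @export
slope_ratio <- function(curve_a, curve_b, eps = 1e-9) {
  common <- intersect(curve_a$s_kb, curve_b$s_kb)
  a <- curve_a$slope[match(common, curve_a$s_kb)]
  b <- curve_b$slope[match(common, curve_b$s_kb)]
  ratio <- ifelse(is.na(b) | abs(b) < eps, NA_real_, a / b)
  data.frame(s_kb = common, slope_a = a, slope_b = b, ratio = ratio)
}

#' Observed/expected transform of a contact map
#'
#' Divides every diagonal by its mean, removing the distance decay so that
#' local structure (loops, insulation) stands out.
#'
#' @param map A [contact_map()].
#' @return An O/E [contact_map()].
#' @export
oe_map <- function(map) {
  stopifnot(inherits(map, "contact_map"))
  m <- map$mat
  n <- nrow(m)
  out <- m
  for (k in 0:(n - 1L)) {
    i <- seq_len(n - k)
    idx <- cbind(i, i + k)
    mu <- mean(m[idx])
    v <- if (mu > 0) m[idx] / mu else 0
    out[idx] <- v
    out[idx[, c(2, 1), drop = FALSE]] <- v
  }
  contact_map(out, map$resolution_kb, normalization = "oe")
}

#' Pile-up of observed/expected contacts around CTCF sites
#'
#' Averages O/E submatrices in windows of `window_kb` on each side of every
#' site; sites closer than the window to a chain end are skipped. Insulation
#' appears as depletion of the off-diagonal quadrants (contacts across the
#' site).
#'
#' @param map A [contact_map()] (raw; the O/E transform is applied
#'   internally, or pass an `"oe"`-normalized map).
#' @param site_beads Integer bead indices of the sites.
#' @param window_kb Half-window (kb), default 100.
#' @return Object of class `pileup`: the averaged square window (odd bin
#'   count, site at the center) with attributes `n_sites`, `window_bins`.
#' @export
pileup <- function(map, site_beads, window_kb = 100) {
  stopifnot(inherits(map, "contact_map"))
  oe <- if (map$normalization == "oe") map else oe_map(map)
  w <- max(1L, round(window_kb / map$resolution_kb))
  n <- nrow(oe$mat)
  use <- site_beads[site_beads - w >= 1 & site_beads + w <= n]
  if (length(use) < length(site_beads)) {
    message(length(site_beads) - length(use),
            " site(s) within a window of a chain end skipped")
  }
  if (!length(use)) stop("no usable sites")
  acc <- matrix(0, 2L * w + 1L, 2L * w + 1L)
  for (b in use) {
    idx <- (b - w):(b + w)
    acc <- acc + oe$mat[idx, idx]
  }
  structure(acc / length(use), class = "pileup", n_sites = length(use),
            window_bins = w, resolution_kb = map$resolution_kb)
}

#' Insulation score of a pile-up
#'
#' Mean O/E contact between loci on opposite sides of the piled-up site
#' (upper-right quadrant of the window). Values below 1 indicate insulation:
#' the site blocks contacts across itself.
#'
#' @param pu A [pileup()].
#' @return Mean cross-site O/E contact.
#' @export
insulation_score <- function(pu) {
  stopifnot(inherits(pu, "pileup"))
  w <- attr(pu, "window_bins")
  ctr <- w + 1L
  mean(pu[seq_len(w), (ctr + 1L):(2L * w + 1L)])
}

#' Map BED intervals to lattice beads
#'
#' Reads a BED file (0-based, half-open) and returns the 1-based bead index
#' of each interval's midpoint at the given resolution. Intervals beyond
#' `chain_length` are dropped.
#'
#' @param path BED file path.
#' @param resolution_kb kb per bead.
#' @param chain_length Optional chain length (beads) to clip against.
#' @return Sorted unique integer bead indices.
#' @export
bed_to_beads <- function(path, resolution_kb, chain_length = NULL) {
  if (requireNamespace("rtracklayer", quietly = TRUE)) {
    gr <- as.data.frame(rtracklayer::import(path, format = "BED"))
    start0 <- gr$start - 1L  # GRanges is 1-based
    end <- gr$end
  } else {
    bed <- utils::read.table(path, sep = "\t", header = FALSE,
                             comment.char = "#")
    start0 <- bed[[2]]
    end <- bed[[3]]
  }
  mid <- floor((start0 + end) / 2)
  beads <- unique(sort(as.integer(mid %/% (resolution_kb * 1000) + 1L)))
  if (!is.null(chain_length)) beads <- beads[beads <= chain_length]
  beads
}

#' Write / read a contact map as a plain text matrix
#'
#' Dense tab-separated matrix with a `#` header line carrying the
#' resolution and normalization.
#'
#' @param map A [contact_map()].
#' @param path File path.
#' @return `read_contact_map` returns the [contact_map()].
#' @export
write_contact_map <- function(map, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("# resolution_kb=%g normalization=%s",
                     map$resolution_kb, map$normalization), con)
  utils::write.table(map$mat, con, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' @rdname write_contact_map
#' @export
read_contact_map <- function(path) {
  hdr <- readLines(path, n = 1L)
  res <- as.numeric(sub(".*resolution_kb=([0-9.eE+-]+).*", "\\1", hdr))
  norm <- sub(".*normalization=(\\S+).*", "\\1", hdr)
  m <- as.matrix(utils::read.table(path, sep = "\t", skip = 1L))
  dimnames(m) <- NULL
  contact_map(m, res, norm)
}
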