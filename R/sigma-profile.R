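#' Construct a sigma profile
#'
#' A sigma profile is the histogram of a molecule's COSMO surface-screening
#' charge density: for each charge-density bin (e/A^2) it records how much
#' cavity surface area (A^2) carries that density. Together with the total
#' cavity area and volume it is the complete input the segment-activity
#' model needs for one molecule.
#'
#' @param name Molecule label.
#' @param p Per-bin surface area, A^2; must be non-negative and sum to `area`.
#' @param area Total cavity surface area, A^2. Defaults to `sum(p)`.
#' @param volume Cavity volume, A^3.
#' @param grid Bin centres, e/A^2; strictly increasing, uniform spacing.
#'   Defaults to the standard 51-point grid on `[-0.025, 0.025]`.
#' @return A `sigma_profile`: a tibble with columns `sigma`, `p` and
#'   attributes `name`, `area`, `volume`.
#' @export
sigma_profile <- function(name, p, area = sum(p), volume, grid = sigma_grid()) {
  validate_sigma_profile(structure(
    tibble(sigma = grid, p = p),
    name = name, area = area, volume = volume,
    class = c("sigma_profile", class(tibble()))))
}

#' The standard sigma grid
#' @param n_bins Number of bins (default 51).
#' @param sigma_max Half-range of the grid in e/A^2 (default 0.025).
#' @return Numeric vector of uniformly spaced bin centres.
#' @export
sigma_grid <- function(n_bins = 51, sigma_max = 0.025) {
  seq(-sigma_max, sigma_max, length.out = n_bins)
}

#' Validate a sigma profile
#' @param profile A `sigma_profile`.
#' @param area_rtol Relative tolerance for `sum(p) == area`.
#' @return The profile, invisibly classed, if valid.
#' @export
validate_sigma_profile <- function(profile, area_rtol = 1e-6) {
  grid <- profile$sigma
  p <- profile$p
  area <- attr(profile, "area")
  if (length(grid) < 2L || any(diff(grid) <= 0)) {
    stop_sfelip("sigma grid must be strictly increasing", "sigma_grid")
  }
  h <- diff(grid)
  if (max(h) - min(h) > 1e-9 * max(h)) {
    stop_sfelip("sigma grid must be uniform", "sigma_grid")
  }
  if (any(p < 0)) stop_sfelip("sigma profile has negative p", "negative_p")
  if (!is_number(area) || abs(sum(p) - area) > area_rtol * max(area, 1)) {
    stop_sfelip(sprintf("sum(p) = %.8g does not match area = %.8g",
                        sum(p), area), "area_mismatch")
  }
  vol <- attr(profile, "volume")
  if (!is_number(vol) || vol <= 0) {
    stop_sfelip("cavity volume must be a positive number", "volume")
  }
  profile
}

#' Read a sigma profile from its text dialect
#'
#' The dialect is plain text: `# name:`, `# area:`, `# volume:` header lines
#' followed by two whitespace-separated columns (bin centre sigma in e/A^2,
#' surface area p in A^2). Chosen for diff-ability and independence from any
#' binary quantum-chemistry output format.
#'
#' @param path Input file.
#' @return A `sigma_profile`.
#' @export
read_sigma_profile <- function(path) {
  lines <- readLines(path)
  hdr <- grep("^#", lines, value = TRUE)
  get <- function(key) {
    m <- grep(sprintf("^#\\s*%s:", key), hdr, value = TRUE)
    if (!length(m)) stop_sfelip(sprintf("missing '# %s:' header", key),
                                "profile_header")
    sub(sprintf("^#\\s*%s:\\s*", key), "", m[1])
  }
  body <- lines[!grepl("^#", lines) & nzchar(trimws(lines))]
  mat <- do.call(rbind, lapply(strsplit(trimws(body), "\\s+"), as.numeric))
  sigma_profile(name = get("name"),
                p = mat[, 2],
                area = as.numeric(get("area")),
                volume = as.numeric(get("volume")),
                grid = mat[, 1])
}

#' Write a sigma profile to its text dialect
#' @param profile A `sigma_profile`.
#' @param path Output file.
#' @return `path`, invisibly.
#' @export
write_sigma_profile <- function(profile, path) {
  profile <- validate_sigma_profile(profile)
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(
    sprintf("# name: %s", attr(profile, "name")),
    sprintf("# area: %.15e", attr(profile, "area")),
    sprintf("# volume: %.15e", attr(profile, "volume")),
    sprintf("% .15e % .15e", profile$sigma, profile$p)
  ), con)
  invisible(path)
}

#' @exportS3Method ggplot2::autoplot
autoplot.sigma_profile <- function(object, ...) {
  ggplot(object, aes(x = .data$sigma, y = .data$p)) +
    geom_col(width = diff(object$sigma[1:2]) * 0.9, fill = "steelblue") +
    labs(x = expression(sigma ~ (e / ring(A)^2)),
         y = expression(p(sigma) ~ (ring(A)^2)),
         title = attr(object, "name")) +
    theme_minimal()
}

#' Spatially average raw COSMO surface segments into a sigma profile
#'
#' Raw COSMO output assigns a screening charge density to many small surface
#' segments. Before histogramming, each segment's density is replaced by a
#' distance-weighted average over its neighbours with the standard averaging
#' kernel of radius `r_av`, which smooths the quantum-chemistry noise that a
#' single tiny segment carries. The averaged densities are then binned onto
#' the uniform grid, splitting each segment's area linearly between the two
#' adjacent bins so that total area and mean density are conserved.
#'
#' @param segments Data frame with columns `x, y, z` (segment positions, A),
#'   `area` (A^2) and `sigma` (e/A^2).
#' @param name Molecule label for the resulting profile.
#' @param volume Cavity volume (A^3) carried into the profile.
#' @param r_av Averaging radius, A.
#' @param grid Target sigma grid.
#' @return A `sigma_profile` with `sum(p)` equal to the total segment area.
#' @export
average_segments <- function(segments, name = "molecule", volume = NULL,
                             r_av = cosmo_parameters()$r_av,
                             grid = sigma_grid()) {
  segments <- as_tibble(segments)
  if (nrow(segments) == 0L) {
    stop_sfelip("empty segment list", "empty_segments")
  }
  rn2 <- segments$area / pi           # squared segment radius
  rav2 <- r_av^2
  pos <- as.matrix(segments[, c("x", "y", "z")])
  d2 <- as.matrix(stats::dist(pos))^2
  w <- (outer(rep(1, nrow(segments)), rn2 * rav2 / (rn2 + rav2))) *
    exp(-d2 / outer(rep(1, nrow(segments)), rn2 + rav2))
  sigma_avg <- as.vector(w %*% segments$sigma) / rowSums(w)
  bin_onto_grid(sigma_avg, segments$area, grid, name = name,
                volume = volume %||% (sum(segments$area)^1.5 / (6 * sqrt(pi))))
}

# Linear split of each (sigma, area) pair between the two flanking bins.
bin_onto_grid <- function(sigma, area, grid, name, volume) {
  h <- grid[2] - grid[1]
  clipped <- sigma < grid[1] | sigma > grid[length(grid)]
  if (any(clipped)) {
    warn(sprintf("%d segment(s) outside the sigma grid were clipped",
                 sum(clipped)))
    sigma <- pmin(pmax(sigma, grid[1]), grid[length(grid)])
  }
  pos <- (sigma - grid[1]) / h
  lo <- pmin(floor(pos), length(grid) - 2)
  frac <- pos - lo
  p <- numeric(length(grid))
  for (i in seq_along(sigma)) {
    p[lo[i] + 1] <- p[lo[i] + 1] + area[i] * (1 - frac[i])
    p[lo[i] + 2] <- p[lo[i] + 2] + area[i] * frac[i]
  }
  sigma_profile(name = name, p = p, area = sum(area), volume = volume,
                grid = grid)
}
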