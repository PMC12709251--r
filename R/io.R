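# Profile file I/O and unit conversions.
#
# Profile files are whitespace/TSV text: "#"-prefixed key=value header lines
# (units, k, kG0, m, gamma, epsilon, lme, seed, ... unknown keys preserved),
# then one row per grid point: z, total [, per-component columns].

.kB <- 1.380649e-23  # J/K

#' Write a stress profile to a text file
#'
#' Tab-separated, 12 significant digits, with `#key=value` metadata header
#' lines and a `#columns=` line naming the columns.  Round-trips losslessly
#' through [read_profile()].
#'
#' @param profile a `stress_profile`.
#' @param path output file path.
#' @return the path, invisibly.
#' @export
write_profile <- function(profile, path) {
  stopifnot(inherits(profile, "stress_profile"))
  con <- file(path, "w")
  on.exit(close(con))
  meta <- profile$meta
  hdr <- c(units = profile$units_tag)
  if (!is.null(profile$params)) {
    p <- profile$params
    hdr <- c(hdr, k = p$k, kG0 = p$kG0, m = p$m, gamma = p$gamma)
  }
  if (!is.null(profile$geom))
    hdr <- c(hdr, epsilon = profile$geom$epsilon, lme = profile$geom$lme)
  for (nm in names(meta)) hdr[nm] <- meta[[nm]]
  for (nm in names(hdr))
    writeLines(sprintf("#%s=%s", nm, format(hdr[[nm]], digits = 12)), con)
  cols <- c("z", names(profile$components), "total")
  writeLines(sprintf("#columns=%s", paste(cols, collapse = "\t")), con)
  m <- cbind(profile$z, as.matrix(profile$components), profile$total)
  # data rows at 15 significant digits so numeric round trips stay inside
  # 1e-12 relative (12 digits would quantize at ~5e-12)
  writeLines(apply(m, 1L, function(r)
    paste(sprintf("%.15g", r), collapse = "\t")), con)
  invisible(path)
}

#' Read a stress profile from a text file
#'
#' @param path input file path (format of [write_profile()]; a bare
#'   two-column z/stress file is also accepted, the single stress column
#'   being taken as the total).
#' @return a `stress_profile`; header metadata lands in `$meta`, and
#'   (k, kG0, m, gamma) / (epsilon, lme) are rebuilt into `$params` /
#'   `$geom` when present.
#' @export
read_profile <- function(path) {
  if (!file.exists(path)) stop(sprintf("no such file: %s", path))
  lines <- readLines(path)
  is_hdr <- startsWith(trimws(lines), "#")
  meta <- list()
  for (h in lines[is_hdr]) {
    h <- sub("^\\s*#", "", h)
    eq <- regexpr("=", h, fixed = TRUE)
    if (eq > 0) {
      key <- trimws(substr(h, 1, eq - 1))
      val <- trimws(substr(h, eq + 1, nchar(h)))
      num <- suppressWarnings(as.numeric(val))
      meta[[key]] <- if (!is.na(num) && key != "columns") num else val
    }
  }
  body_idx <- which(!is_hdr & nzchar(trimws(lines)))
  if (length(body_idx) == 0L)
    stop(sprintf("empty profile: %s has no data rows", path))
  rows <- strsplit(trimws(lines[body_idx]), "[\t ]+")
  ncol_ <- length(rows[[1L]])
  if (ncol_ < 2L)
    stop(sprintf("line %d: need at least two columns (z, stress)", body_idx[1L]))
  mat <- matrix(NA_real_, length(rows), ncol_)
  for (i in seq_along(rows)) {
    if (length(rows[[i]]) != ncol_)
      stop(sprintf("line %d: expected %d columns, found %d",
                   body_idx[i], ncol_, length(rows[[i]])))
    v <- suppressWarnings(as.numeric(rows[[i]]))
    if (anyNA(v))
      stop(sprintf("line %d: non-numeric value '%s'",
                   body_idx[i], rows[[i]][which(is.na(v))[1L]]))
    mat[i, ] <- v
  }
  z <- mat[, 1L]
  bad <- which(diff(z) <= 0)
  if (length(bad))
    stop(sprintf("line %d: z not strictly increasing (%.6g after %.6g)",
                 body_idx[bad[1L] + 1L], z[bad[1L] + 1L], z[bad[1L]]))
  colnames_ <- if (!is.null(meta$columns))
    strsplit(meta$columns, "[\t ]+")[[1L]] else NULL
  if (!is.null(colnames_) && length(colnames_) == ncol_) {
    comp_idx <- which(!(colnames_ %in% c("z", "total")))
    comps <- as.data.frame(mat[, comp_idx, drop = FALSE])
    names(comps) <- colnames_[comp_idx]
  } else {
    comps <- data.frame(total = mat[, 2L])
  }
  params <- NULL
  if (all(c("k", "kG0", "m", "gamma") %in% names(meta)))
    params <- elastic_constants(meta$k, meta$kG0, meta$m, meta$gamma)
  geom <- NULL
  if ("epsilon" %in% names(meta)) {
    geom <- if ("lme" %in% names(meta))
      interface_geometry(lme = meta$lme, epsilon = meta$epsilon)
    else interface_geometry(epsilon = meta$epsilon)
  }
  units_tag <- if (!is.null(meta$units)) meta$units else "kbt_nm3"
  meta[c("units", "columns", "k", "kG0", "m", "gamma", "epsilon", "lme")] <- NULL
  new_stress_profile(z, comps, units_tag, params, geom, meta)
}

unit_families <- list(
  stress = c(kbt_nm3 = NA, bar = 1e5, Pa = 1),            # to Pa
  tension = c(kbt_nm2 = NA, mN_m = 1e-3, N_m = 1),        # to N/m
  energy = c(kBT = NA, kJ_mol = 1e3 / 6.02214076e23, J = 1))  # to J

#' Convert stresses, tensions or energies between unit systems
#'
#' Exact linear conversions within a unit family: stresses
#' (`kbt_nm3`, `bar`, `Pa`), tensions (`kbt_nm2`, `mN_m`, `N_m`) and
#' energies (`kBT`, `kJ_mol`, `J`).  kBT-based units require a temperature;
#' 1 kbt_nm3 = kB*T / 1e-27 Pa (about 41.4 bar at 300 K) and
#' 1 kbt_nm2 = kB*T / 1e-18 N/m (about 4.14 mN/m at 300 K).
#'
#' @param value numeric value(s) to convert.
#' @param from,to unit names from the same family.
#' @param temperature kelvin; needed iff a kBT-based unit is involved
#'   (default 298.15).
#' @return converted value(s).
#' @export
convert_stress <- function(value, from, to, temperature = 298.15) {
  fam <- NULL
  for (f in names(unit_families))
    if (from %in% names(unit_families[[f]])) fam <- f
  if (is.null(fam)) stop(sprintf("unknown unit '%s'", from))
  if (!(to %in% names(unit_families[[fam]])))
    stop(sprintf("cannot convert '%s' to '%s': different unit families", from, to))
  if (!(is.numeric(temperature) && temperature > 0))
    stop("`temperature` must be positive (kelvin)")
  kbt_si <- switch(fam,
                   stress = .kB * temperature / 1e-27,
                   tension = .kB * temperature / 1e-18,
                   energy = .kB * temperature)
  f_si <- unit_families[[fam]]
  to_si <- function(u) if (is.na(f_si[[u]])) kbt_si else f_si[[u]]
  value * to_si(from) / to_si(to)
}

#' Export the curve data behind the package's standard figure set
#'
#' Six families of curves at the canonical parameters (k = 20 kBT, default
#' geometry lme = 6 epsilon = 5 nm):
#' \describe{
#'   \item{1}{normalized bending components sB2/k, sB1/(mk), sB0/(m^2 k)}
#'   \item{2}{normalized Gaussian component sG/kG0}
#'   \item{3}{total s(z) at kG0 = -0.7k, gamma = 0, m in 0, +0.1, -0.1 1/nm}
#'   \item{4}{total s(z), m = 0, kG0/k in -0.6, -24/35, -0.7, -0.8, -1}
#'   \item{5a}{tension component sT at gamma = 0.01, 0.02, 0.04 mN/m}
#'   \item{5b}{total s(z) (kG0 = -0.7k, m = 0) at lme = 4.5, 4.75, 5 nm}
#'   \item{6}{total s(z) at kG0 = -0.8k, gamma = 0, m in 0, +0.1, -0.1 1/nm}
#' }
#'
#' @param figure_id one of "1", "2", "3", "4", "5a", "5b", "6" (integers
#'   accepted; 5 means both 5a and 5b).
#' @param outdir directory to write TSV curve files into, or NULL to return
#'   the profiles without writing.
#' @param n grid points per curve.
#' @param z_range half-width of the z grid (nm).
#' @param temperature kelvin, for the mN/m tensions of figure 5a.
#' @return named list of `stress_profile` objects (invisibly if written).
#' @export
export_figure_data <- function(figure_id, outdir = NULL, n = 401L,
                               z_range = 4, temperature = 298.15) {
  fid <- tolower(as.character(figure_id))
  if (fid == "5") fid <- c("5a", "5b")
  valid <- c("1", "2", "3", "4", "5a", "5b", "6")
  if (!all(fid %in% valid))
    stop(sprintf("unknown figure id '%s' (valid: %s)",
                 paste(figure_id, collapse = ","), paste(valid, collapse = ", ")))
  geom <- interface_geometry()
  zr <- c(-z_range, z_range)
  curves <- list()
  add <- function(name, params, g = geom, fig = fid[1L]) {
    p <- sample_profile(params, g, zr[1], zr[2], n)
    p$meta$figure <- fig
    p$meta$curve <- name
    curves[[name]] <<- p
  }
  for (f in fid) {
    if (f == "1") {
      g1 <- geom
      add("fig1_sB2_over_k", elastic_constants(k = 1, kG0 = 0), fig = f)
      add("fig1_sB1_over_mk", elastic_constants(k = 1, kG0 = 0, m = 1), fig = f)
      add("fig1_sB0_over_m2k", elastic_constants(k = 1, kG0 = 0, m = 1), fig = f)
      # keep only the named component as total for the normalized curves
      curves[["fig1_sB2_over_k"]]$components[c("sB1", "sB0", "sG", "sT")] <- 0
      curves[["fig1_sB1_over_mk"]]$components[c("sB2", "sB0", "sG", "sT")] <- 0
      curves[["fig1_sB0_over_m2k"]]$components[c("sB2", "sB1", "sG", "sT")] <- 0
      for (nm in grep("^fig1", names(curves), value = TRUE))
        curves[[nm]]$total <- rowSums(curves[[nm]]$components)
    } else if (f == "2") {
      add("fig2_sG_over_kG", elastic_constants(k = 1e-12, kG0 = 1), fig = f)
      curves[["fig2_sG_over_kG"]]$components[c("sB2", "sB1", "sB0", "sT")] <- 0
      curves[["fig2_sG_over_kG"]]$total <-
        rowSums(curves[["fig2_sG_over_kG"]]$components)
    } else if (f == "3") {
      for (m in c(0, 0.1, -0.1))
        add(sprintf("fig3_m_%+g", m),
            elastic_constants(k = 20, kG0 = -0.7 * 20, m = m), fig = f)
    } else if (f == "4") {
      for (r in c(-0.6, -24 / 35, -0.7, -0.8, -1))
        add(sprintf("fig4_kGratio_%.6f", r),
            elastic_constants(k = 20, kG0 = r * 20), fig = f)
    } else if (f == "5a") {
      for (g_mN in c(0.01, 0.02, 0.04)) {
        gam <- convert_stress(g_mN, "mN_m", "kbt_nm2", temperature)
        add(sprintf("fig5a_gamma_%g_mNm", g_mN),
            elastic_constants(k = 20, kG0 = 0, gamma = gam), fig = f)
        nm <- sprintf("fig5a_gamma_%g_mNm", g_mN)
        curves[[nm]]$components[c("sB2", "sB1", "sB0", "sG")] <- 0
        curves[[nm]]$total <- rowSums(curves[[nm]]$components)
      }
    } else if (f == "5b") {
      for (l in c(4.5, 4.75, 5))
        add(sprintf("fig5b_lme_%g", l),
            elastic_constants(k = 20, kG0 = -0.7 * 20),
            g = interface_geometry(lme = l), fig = f)
    } else if (f == "6") {
      for (m in c(0, 0.1, -0.1))
        add(sprintf("fig6_m_%+g", m),
            elastic_constants(k = 20, kG0 = -0.8 * 20, m = m), fig = f)
    }
  }
  if (!is.null(outdir)) {
    if (!dir.exists(outdir)) dir.create(outdir, recursive = TRUE)
    for (nm in names(curves))
      write_profile(curves[[nm]], file.path(outdir, paste0(nm, ".tsv")))
    return(invisible(curves))
  }
  curves
}
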