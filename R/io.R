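# Configuration files, structured sweep output, and the Fig.-style plot.
# Config files are YAML with the sections geometry / physics / protocol /
# integrator / output; every field can be overridden programmatically (or
# by CLI flag through the bundled entry point in inst/cli/).

.config_fields <- list(
  geometry = c("L", "h_max", "h_min", "omega", "area_exponent"),
  physics = c("D", "T", "f_mu"),
  protocol = c("n_particles", "max_time", "boundary_mode", "phase0",
               "entrance_offset"),
  integrator = c("dt_tilde", "m_tilde", "backend"),
  output = c("seed")
)

#' Load a run configuration from a YAML file
#'
#' The file may contain any subset of the sections `geometry`, `physics`,
#' `protocol`, `integrator`, `output`; missing fields take the
#' [run_config()] defaults, unknown sections or keys are rejected by
#' name. An empty file yields the full default configuration.
#'
#' @param path path to a YAML config file.
#' @param overrides named list applied on top of the file (CLI flags).
#' @return A validated [run_config()].
#' @export
load_config <- function(path, overrides = list()) {
  raw <- yaml::read_yaml(path)
  if (is.null(raw)) raw <- list()
  if (!is.list(raw))
    stop(sprintf("parse error: '%s' is not a YAML mapping", path),
         call. = FALSE)
  bad <- setdiff(names(raw), names(.config_fields))
  if (length(bad))
    stop("unknown config section(s): ", paste(bad, collapse = ", "),
         call. = FALSE)
  flat <- list()
  for (sec in names(raw)) {
    keys <- names(raw[[sec]])
    unknown <- setdiff(keys, .config_fields[[sec]])
    if (length(unknown))
      stop(sprintf("unknown key(s) in [%s]: %s", sec,
                   paste(unknown, collapse = ", ")), call. = FALSE)
    flat[keys] <- raw[[sec]]
  }
  flat[names(overrides)] <- overrides
  do.call(run_config, flat)
}

#' Reproducibility metadata of a run
#'
#' @param config the [run_config()] used.
#' @param extra named list merged into the record.
#' @return A list ready for JSON serialization; rerunning the package
#'   with this config and seed reproduces the associated table
#'   bit-exactly.
#' @export
run_metadata <- function(config, extra = list()) {
  cfg <- unclass(config)
  cfg$phase0 <- if (is.null(cfg$phase0)) NA else cfg$phase0
  c(list(package = "entropore",
         version = as.character(packageVersion("entropore")),
         timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"),
         config = cfg),
    extra)
}

#' Write a frequency sweep to disk
#'
#' Writes `<name>.tsv` (9-significant-digit TSV with the fixed column
#' contract `omega_dimless`, `f_mu`, `gamma_dimless`, `stderr`,
#' `gamma_physical_per_s`, `n_success`, `n_total`, `success_fraction`)
#' and `<name>.meta.json` (seed, full config, version). Optionally also
#' `<name>.png` with the rate-vs-frequency curves.
#'
#' @param sweep an `entropore_sweep` from [sweep_frequency()].
#' @param dir output directory (created if missing).
#' @param name file stem.
#' @param plot also write a PNG of the sweep.
#' @return Invisibly, the paths written.
#' @export
write_sweep <- function(sweep, dir = ".", name = "sweep", plot = FALSE) {
  stopifnot(inherits(sweep, "entropore_sweep"))
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  config <- attr(sweep, "config")
  tab <- as.data.frame(sweep)
  tab$gamma_physical_per_s <- to_physical_rate(tab$gamma_dimless,
                                               D = config$D, L = config$L)
  tab <- tab[, c("omega_dimless", "f_mu", "gamma_dimless", "stderr",
                 "gamma_physical_per_s", "n_success", "n_total",
                 "success_fraction")]
  num <- vapply(tab, is.double, logical(1))
  tab[num] <- lapply(tab[num], signif, digits = 9)
  tsv <- file.path(dir, paste0(name, ".tsv"))
  write.table(tab, tsv, sep = "\t", quote = FALSE, row.names = FALSE)
  meta <- file.path(dir, paste0(name, ".meta.json"))
  jsonlite::write_json(run_metadata(config,
                                    list(n_cells = nrow(tab))),
                       meta, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  paths <- c(tsv = tsv, meta = meta)
  if (plot) {
    png_path <- file.path(dir, paste0(name, ".png"))
    grDevices::png(png_path, width = 900, height = 600, res = 110)
    plot(sweep)
    grDevices::dev.off()
    paths <- c(paths, plot = png_path)
  }
  invisible(paths)
}

#' Read a sweep TSV back into R
#'
#' @param path a TSV written by [write_sweep()].
#' @return A data.frame (without the config attribute).
#' @export
read_sweep <- function(path) {
  read.delim(path, sep = "\t", check.names = FALSE)
}

#' Plot a frequency sweep
#'
#' Transport rate versus dimensionless frequency on a logarithmic
#' frequency axis, one curve per `f_mu`, with +/- 1 standard-error bars.
#'
#' @param x an `entropore_sweep`.
#' @param ... passed to [graphics::matplot()].
#' @export
plot.entropore_sweep <- function(x, ...) {
  fms <- sort(unique(x$f_mu))
  cols <- grDevices::hcl.colors(max(3, length(fms)), "Dark 3")
  rng <- range(x$gamma_dimless + x$stderr, x$gamma_dimless - x$stderr,
               na.rm = TRUE)
  graphics::plot(NA, xlim = range(x$omega_dimless), ylim = rng, log = "x",
                 xlab = expression(omega * L^2 / D),
                 ylab = expression(tilde(Gamma)),
                 main = "Transport rate vs breathing frequency", ...)
  for (i in seq_along(fms)) {
    s <- x[x$f_mu == fms[i], ]
    s <- s[order(s$omega_dimless), ]
    graphics::lines(s$omega_dimless, s$gamma_dimless, col = cols[i],
                    type = "b", pch = 16, cex = 0.6)
    graphics::arrows(s$omega_dimless, s$gamma_dimless - s$stderr,
                     s$omega_dimless, s$gamma_dimless + s$stderr,
                     angle = 90, code = 3, length = 0.02, col = cols[i])
  }
  graphics::legend("bottomleft", legend = sprintf("f_mu = %g", fms),
                   col = cols[seq_along(fms)], lty = 1, pch = 16, bty = "n")
  invisible(x)
}
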