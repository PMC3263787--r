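#' Write a results table as TSV with a metadata header
#'
#' Plain TSV preceded by \code{#}-prefixed \code{key: value} metadata lines
#' (tool version, seed, whatever the caller supplies) -- diff-friendly and
#' parseable everywhere.
#'
#' @param df data frame to write.
#' @param path output file.
#' @param meta named list of metadata scalars.
#' @return \code{path}, invisibly.
#' @export
write_table_tsv <- function(df, path, meta = list()) {
  meta <- c(list(package = paste0("neonirs ",
                                  as.character(utils::packageVersion("neonirs"))),
                 written = format(Sys.time(), "%Y-%m-%dT%H:%M:%S")),
            meta)
  con <- file(path, "w")
  on.exit(close(con))
  for (nm in names(meta))
    writeLines(sprintf("# %s: %s", nm, format(meta[[nm]])), con)
  utils::write.table(df, con, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a TSV written by \code{\link{write_table_tsv}}
#'
#' @param path input file.
#' @return data frame; the parsed metadata is attached as attribute
#'   \code{"meta"} (named character vector).
#' @export
read_table_tsv <- function(path) {
  lines <- readLines(path)
  is_meta <- grepl("^#", lines)
  header <- sub("^# *", "", lines[is_meta & cumsum(!is_meta) == 0])
  keys <- sub(":.*$", "", header)
  vals <- trimws(sub("^[^:]*: *", "", header))
  df <- utils::read.table(text = lines[!is_meta], sep = "\t", header = TRUE,
                          stringsAsFactors = FALSE)
  attr(df, "meta") <- stats::setNames(vals, keys)
  df
}

#' Write a JSON metadata sidecar
#'
#' @param meta named list (settings, seeds, runtimes, ...).
#' @param path output file, conventionally \code{<table>.json}.
#' @return \code{path}, invisibly.
#' @export
write_json_sidecar <- function(meta, path) {
  jsonlite::write_json(meta, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}

#' Serialize a medium, chromophore table and wavelengths to a config file
#'
#' YAML with blocks \code{medium} (layers surface-first plus
#' \code{n_ambient}), \code{chromophores} and \code{wavelengths}; units as
#' in the constructors (mm, uM, percent, mm^-1, nm).  The round trip
#' through \code{\link{read_medium_config}} is lossless.
#'
#' @param medium a \code{\link{layered_medium}}.
#' @param table a \code{\link{chromophore_table}}.
#' @param wavelengths simulation wavelengths, nm.
#' @param path output file.
#' @param reference_wavelength nm for the scattering model.
#' @return \code{path}, invisibly.
#' @export
write_medium_config <- function(medium, table, wavelengths, path,
                                reference_wavelength = 760) {
  stopifnot(inherits(medium, "layered_medium"),
            inherits(table, "chromophore_table"))
  cfg <- list(
    medium = list(
      n_ambient = medium$n_ambient,
      layers = lapply(medium$layers, function(l) {
        l <- unclass(l)
        if (is.infinite(l$thickness)) l$thickness <- "Inf"
        l
      })),
    chromophores = list(wavelengths = table$wavelengths,
                        eps_hbo2 = table$eps_hbo2,
                        eps_hhb = table$eps_hhb,
                        mua_water = table$mua_water),
    wavelengths = wavelengths,
    reference_wavelength = reference_wavelength)
  yaml::write_yaml(cfg, path, precision = 15)
  invisible(path)
}

#' Read a medium/chromophore config file
#'
#' @param path YAML (or JSON, a YAML subset) config as written by
#'   \code{\link{write_medium_config}}; every block is validated through the
#'   package constructors, so malformed configs fail with the constructors'
#'   explicit messages.
#' @return list with \code{medium}, \code{table}, \code{wavelengths},
#'   \code{reference_wavelength}.
#' @export
read_medium_config <- function(path) {
  cfg <- yaml::read_yaml(path)
  for (block in c("medium", "chromophores", "wavelengths"))
    if (is.null(cfg[[block]]))
      stop("config is missing the '", block, "' block", call. = FALSE)
  if (is.null(cfg$medium$layers) || length(cfg$medium$layers) == 0)
    stop("config 'medium' block has no layers", call. = FALSE)
  layers <- lapply(cfg$medium$layers, function(l) {
    l$thickness <- if (identical(l$thickness, "Inf")) Inf
                   else as.numeric(l$thickness)
    do.call(tissue_layer, l[c("thickness", "hb_total", "so2",
                              "water_fraction", "musp_ref", "musp_slope",
                              "g", "n_refr")])
  })
  medium <- layered_medium(layers,
                           n_ambient = cfg$medium$n_ambient %||% 1.0)
  table <- chromophore_table(
    wavelengths = as.numeric(cfg$chromophores$wavelengths),
    eps_hbo2 = as.numeric(cfg$chromophores$eps_hbo2),
    eps_hhb = as.numeric(cfg$chromophores$eps_hhb),
    mua_water = as.numeric(cfg$chromophores$mua_water))
  list(medium = medium, table = table,
       wavelengths = as.numeric(cfg$wavelengths),
       reference_wavelength = cfg$reference_wavelength %||% 760)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
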