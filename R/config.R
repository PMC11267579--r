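# Configuration documents: a TOML file with [field], [run], [loss],
# [prs], [optimizer] and [chi] tables plus optional [[system]] entries.
# Unknown keys are rejected; defaults mirror the engine's standard
# simulation protocol and are documented in the shipped default file
# (inst/extdata/default-config.toml).

config_schema <- list(
  field = c("grid", "rho0", "kappa", "a", "sigma", "epsr", "coulomb",
            "order"),
  run = c("dt_inner", "dt_outer", "temperature", "tau_t", "pressure",
          "tau_p", "barostat", "beta_c", "n_equil", "n_traced", "stride",
          "seed"),
  loss = c("w_t", "w_A", "dchi_max", "h", "center"),
  prs = c("n_replicas", "n_equil", "n_traced", "stride", "max_failures"),
  optimizer = c("eta", "b1", "b2", "epochs", "eps"),
  chi = NULL, # free-form species-pair keys "A-B"
  system = c("topology", "coordinates", "reference_profile",
             "reference_apl", "temperature", "name")
)

check_keys <- function(tbl, section) {
  allowed <- config_schema[[section]]
  if (is.null(allowed)) return(invisible())
  extra <- setdiff(names(tbl), allowed)
  if (length(extra))
    stop("unknown key(s) in [", section, "]: ",
         paste(extra, collapse = ", "))
  invisible()
}

#' Read and validate a configuration document
#'
#' Parses the TOML file, rejects unknown keys, and instantiates the
#' configuration objects with defaults for everything unspecified.
#'
#' @param path TOML file path.
#' @return list with `field_cfg`, `run_cfg`, `loss`, `prs_cfg`,
#'   `optimizer_cfg`, `chi_pairs` (data.frame or NULL) and `systems`
#'   (list of raw system tables).
#' @export
read_config <- function(path) {
  doc <- read_toml(path)
  unknown <- setdiff(names(doc), names(config_schema))
  if (length(unknown))
    stop("unknown configuration section(s): ",
         paste(unknown, collapse = ", "))
  for (sec in intersect(names(doc), c("field", "run", "loss", "prs",
                                      "optimizer")))
    check_keys(doc[[sec]], sec)
  for (sys in doc$system) check_keys(sys, "system")

  field_cfg <- do.call(field_config, modifyList(
    list(), doc$field %||% list()))
  run_args <- doc$run %||% list()
  if (!is.null(run_args$temperature) && is.character(run_args$temperature))
    run_args$temperature <- as.numeric(run_args$temperature)
  run_cfg <- do.call(run_config, run_args)
  prs_cfg <- do.call(prs_config, doc$prs %||% list())
  optimizer_cfg <- do.call(optimizer_config, doc$optimizer %||% list())
  loss <- doc$loss %||% list()

  chi_pairs <- NULL
  if (!is.null(doc$chi) && length(doc$chi)) {
    nm <- names(doc$chi)
    ab <- strsplit(nm, "-", fixed = TRUE)
    chi_pairs <- data.frame(a = vapply(ab, `[`, "", 1),
                            b = vapply(ab, `[`, "", 2),
                            chi = as.numeric(unlist(doc$chi)))
  }
  list(field_cfg = field_cfg, run_cfg = run_cfg, loss = loss,
       prs_cfg = prs_cfg, optimizer_cfg = optimizer_cfg,
       chi_pairs = chi_pairs, systems = doc$system %||% list())
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Write a configuration document
#'
#' Serialises configuration objects to TOML; `read_config()` of the result
#' reproduces them.
#'
#' @param cfg list as returned by [read_config()] (any subset of its
#'   elements).
#' @param path output path.
#' @export
write_config <- function(cfg, path) {
  doc <- list()
  if (!is.null(cfg$field_cfg))
    doc$field <- unclass(cfg$field_cfg)
  if (!is.null(cfg$run_cfg)) {
    rc <- unclass(cfg$run_cfg)
    rc$n_inner <- NULL
    doc$run <- rc
  }
  if (!is.null(cfg$loss) && length(cfg$loss)) doc$loss <- cfg$loss
  if (!is.null(cfg$prs_cfg)) doc$prs <- unclass(cfg$prs_cfg)
  if (!is.null(cfg$optimizer_cfg))
    doc$optimizer <- unclass(cfg$optimizer_cfg)
  if (!is.null(cfg$chi_pairs)) {
    ch <- as.list(cfg$chi_pairs$chi)
    names(ch) <- paste0(cfg$chi_pairs$a, "-", cfg$chi_pairs$b)
    doc$chi <- ch
  }
  if (!is.null(cfg$systems) && length(cfg$systems))
    doc$system <- cfg$systems
  # drop NULL/NA-valued entries the TOML writer cannot represent
  clean <- function(x) {
    if (!is.list(x)) return(x)
    x <- x[!vapply(x, function(v)
      is.null(v) || (length(v) == 1 && !is.list(v) && is.na(v)),
      logical(1))]
    lapply(x, clean)
  }
  write_toml(clean(doc), path)
}
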