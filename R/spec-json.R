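#' Write a simulation spec to JSON
#'
#' Serialises `species_tree_spec`, `hky_params`, `ils_gradient_spec` and
#' `satellite_spec` objects; the class is stored so [read_spec_json()]
#' can restore and re-validate the object.
#'
#' @param spec a spec object.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_spec_json <- function(spec, path) {
  cls <- class(spec)[1]
  if (!cls %in% c("species_tree_spec", "hky_params", "ils_gradient_spec",
                  "satellite_spec"))
    stop("unsupported spec class: ", cls)
  x <- unclass(spec)
  if (cls == "species_tree_spec") {
    x$tree <- ape::write.tree(x$tree)
    x$node_time <- NULL
    # named vectors must become objects, not arrays, to keep their names
    x$split_times <- as.list(x$split_times)
    x$ancestral_ne <- as.list(x$ancestral_ne)
  }
  jsonlite::write_json(c(list(spec_class = cls), x), path,
                       auto_unbox = TRUE, digits = NA, null = "null")
  invisible(path)
}

#' Read a simulation spec from JSON
#'
#' @param path path written by [write_spec_json()].
#' @return the restored, re-validated spec object.
#' @export
read_spec_json <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  cls <- x$spec_class
  switch(cls,
    species_tree_spec = species_tree_spec(
      x$tree, unlist(x$split_times), unlist(x$ancestral_ne),
      x$generation_time, x$mutation_rate),
    hky_params = hky_params(x$kappa, unlist(x$base_freqs),
                            x$gamma_shape, x$n_rate_categories),
    ils_gradient_spec = ils_gradient_spec(
      x$breakpoint, x$background_discordance, x$flank_fold,
      x$flank_span %||% Inf),
    satellite_spec = satellite_spec(x$monomer, unlist(x$array_lengths),
                                    x$spacer_mode, x$spacer_spread,
                                    x$divergence),
    stop("unknown spec class in file: ", cls))
}
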