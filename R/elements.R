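#' Element property table
#'
#' Fixed table of per-element constants consumed by the QNA and
#' whole-molecule descriptors: first ionization potential `IP` and electron
#' affinity `EA` (eV), van der Waals radius `radius` (Angstrom), atomic
#' `mass` (Da), an additive lipophilicity increment `logp_contrib`
#' (dimensionless) and hydrogen-bond donor/acceptor flags `hbd`/`hba`.
#' Values are drawn from standard element-data compilations; the table is
#' shipped as a CSV data file so users can substitute their own.
#'
#' `IP > EA` is required for every element so that the QNA quantity
#' `B = (IP - EA)^(-1/2)` is real; this is validated at load time.
#'
#' @param path Optional path to an alternative CSV with the same columns.
#' @return A data.frame with one row per supported element, rownames set to
#'   the element symbol.
#' @export
#' @examples
#' element_properties()["C", "IP"]
element_properties <- function(path = NULL) {
  default <- is.null(path)
  if (default) {
    if (!is.null(.ao_cache$elements)) return(.ao_cache$elements)
    path <- system.file("extdata", "element_properties.csv", package = "aoqsar")
  }
  tab <- utils::read.csv(path, stringsAsFactors = FALSE)
  required <- c("element", "IP", "EA", "radius", "mass", "logp_contrib", "hbd", "hba")
  if (!all(required %in% names(tab))) {
    stop("element property table must have columns: ", paste(required, collapse = ", "))
  }
  if (any(tab$IP <= tab$EA)) {
    stop("degenerate element entry: IP <= EA for ",
         paste(tab$element[tab$IP <= tab$EA], collapse = ", "))
  }
  if (any(tab$radius <= 0)) stop("element radii must be positive")
  rownames(tab) <- tab$element
  if (default) .ao_cache$elements <- tab
  tab
}
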