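#' Regenerate a packaged synthetic fixture
#'
#' The package ships fixture *parameter files* (JSON under
#' `inst/extdata/`), not coordinate data: every fixture is regenerated
#' bit-reproducibly from its recorded parameters and seed. This keeps the
#' package free of binary payloads while giving tests and examples a stable,
#' named dataset.
#'
#' @param name fixture name, e.g. `"metastable_k3"`; see
#'   `list.files(system.file("extdata", package = "mdconverge"))`.
#' @return list with `trajectory`, `truth`, and `params` (the parsed
#'   parameter document).
#' @examples
#' fx <- packagedFixture("metastable_k3")
#' nFrames(fx$trajectory)
#' @export
packagedFixture <- function(name) {
  file <- system.file("extdata", paste0(name, ".json"), package = "mdconverge")
  if (!nzchar(file)) .stopf("no packaged fixture named '%s'", name)
  p <- jsonlite::read_json(file, simplifyVector = TRUE)
  if (!identical(p$generator, "simulateMetastable"))
    .stopf("unsupported fixture generator '%s'", p$generator)
  tpl <- makeDimerTemplate(p$template$nResPerHelix, p$template$gaugeSeparation,
                           p$template$nLoopRes)
  out <- simulateMetastable(tpl, K = p$K,
                            transitionMatrix = cyclicTransitionMatrix(p$K, p$switchProb),
                            sigma = p$sigma, nFrames = p$nFrames, seed = p$seed,
                            rmsdFloor = p$rmsdFloor, dt = p$dt)
  out$params <- p
  out$template <- tpl
  out
}
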