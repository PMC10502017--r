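#' Built-in device schemas
#'
#' `hingeSchema()`: a two-arm hinge with keypoints `tipA`, `vertex`, `tipB`
#' and one angle (tipA-vertex-tipB).
#'
#' `hingeNucleosomeSchema()`: the hinge plus a `nucleosome` position-only
#' point (a compact blob attached near an arm).
#'
#' `steriDynSchema()`: a two-arm device on a base with keypoints `tipL`,
#' `vertexL`, `vertexR`, `tipR` and two angles, each arm measured against
#' the base segment joining the two vertices: angle L = tipL-vertexL-vertexR,
#' angle R = tipR-vertexR-vertexL. This convention (arms against the base)
#' is one interpretation of a four-point, two-angle device; supply your own
#' [deviceSchema()] to use a different one.
#'
#' @return a [DeviceSchema-class].
#' @export
hingeSchema <- function() {
  deviceSchema("hinge", c("tipA", "vertex", "tipB"),
               angleDefs = list(c("tipA", "vertex", "tipB")))
}

#' @rdname hingeSchema
#' @export
hingeNucleosomeSchema <- function() {
  deviceSchema("hinge-nucleosome",
               c("tipA", "vertex", "tipB", "nucleosome"),
               angleDefs = list(c("tipA", "vertex", "tipB")),
               positionPoints = "nucleosome")
}

#' @rdname hingeSchema
#' @export
steriDynSchema <- function() {
  deviceSchema("steridyn", c("tipL", "vertexL", "vertexR", "tipR"),
               angleDefs = list(c("tipL", "vertexL", "vertexR"),
                                c("tipR", "vertexR", "vertexL")))
}

#' Look up a built-in schema by name
#'
#' @param name one of `"hinge"`, `"hinge-nucleosome"`, `"steridyn"`.
#' @return a [DeviceSchema-class].
#' @export
getSchema <- function(name) {
  switch(name,
         "hinge" = hingeSchema(),
         "hinge-nucleosome" = hingeNucleosomeSchema(),
         "steridyn" = steriDynSchema(),
         stop("unknown schema '", name, "'"))
}
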