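# shared fixture builders; everything is generated in code at test time

# a single-voxel acquisition series with arbitrary frame values
voxelSeries <- function(values, meta) {
  new("AcquisitionSeries",
      imageData = array(values, c(1, 1, 1, length(values))),
      meta = meta)
}

# compact metas for unit tests that do not need the full protocol
teMeta <- function(te = c(11, 33, 55, 77, 99), averages = 1) {
  new("SequenceMeta", contrast = "multi_echo", flipAngle = 90, tr = 4000,
      variableName = "TE", variableValues = te, averages = averages,
      voxelSize = c(0.234, 0.234), sliceThickness = 1.5)
}

tiMeta <- function(ti = 90 + (0:59) * 144, averages = 1) {
  new("SequenceMeta", contrast = "ir_truefisp", flipAngle = 60, tr = 4.5,
      variableName = "TI", variableValues = ti, averages = averages,
      voxelSize = c(0.234, 0.234), sliceThickness = 1.5)
}

# square polygon covering columns x1..x2, rows y1..y2 (voxel centres)
squarePolygon <- function(x1, x2, y1, y2) {
  cbind(x = c(x1 - 0.4, x2 + 0.4, x2 + 0.4, x1 - 0.4),
        y = c(y1 - 0.4, y1 - 0.4, y2 + 0.4, y2 + 0.4))
}

# constant-valued ParameterMap on an nr x nc grid
constantMap <- function(value, nr = 20, nc = 20, parameter = "T1",
                        units = "ms") {
  vals <- array(value, c(nr, nc))
  hepamri:::.newParameterMap(parameter, vals, units, array(TRUE, c(nr, nc)))
}
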