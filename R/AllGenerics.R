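## Generics. Accessors are preferred over direct slot access throughout.

#' @rdname VoxelVolume
#' @export
setGeneric("voxelData", function(x) standardGeneric("voxelData"))

#' @rdname VoxelVolume
#' @export
setGeneric("voxelSpacing", function(x) standardGeneric("voxelSpacing"))

#' @rdname VoxelVolume
#' @export
setGeneric("voxelOrigin", function(x) standardGeneric("voxelOrigin"))

#' @rdname segmentBlock-VoxelVolume-method
#' @export
setGeneric("segmentBlock",
  function(volume, ...) standardGeneric("segmentBlock"))

#' @rdname segmentCavity-VoxelVolume-BinaryMask-method
#' @export
setGeneric("segmentCavity",
  function(volume, blockMask, ...) standardGeneric("segmentCavity"))

#' @rdname segmentFragments-VoxelVolume-method
#' @export
setGeneric("segmentFragments",
  function(volume, ...) standardGeneric("segmentFragments"))

#' @rdname maskVolume-BinaryMask-method
#' @export
setGeneric("maskVolume", function(mask) standardGeneric("maskVolume"))

#' @rdname areaProfile-BinaryMask-method
#' @export
setGeneric("areaProfile", function(mask, ...) standardGeneric("areaProfile"))

#' @rdname principalAxis-BinaryMask-method
#' @export
setGeneric("principalAxis", function(mask, ...) standardGeneric("principalAxis"))

#' @rdname deflectionAngle-BinaryMask-BinaryMask-method
#' @export
setGeneric("deflectionAngle",
  function(cavityMask, blockMask, ...) standardGeneric("deflectionAngle"))

#' @rdname maxInscribedSphere-BinaryMask-method
#' @export
setGeneric("maxInscribedSphere",
  function(mask, ...) standardGeneric("maxInscribedSphere"))

#' @rdname FragmentSet-class
#' @export
setGeneric("fragmentTable", function(x) standardGeneric("fragmentTable"))

#' @rdname FragmentSet-class
#' @export
setGeneric("countedFragments", function(x) standardGeneric("countedFragments"))

#' @rdname buildConeModel
#' @export
setGeneric("coneVolume", function(model) standardGeneric("coneVolume"))

#' @rdname coneAreaProfile-ConeModel-method
#' @export
setGeneric("coneAreaProfile",
  function(model, ...) standardGeneric("coneAreaProfile"))
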