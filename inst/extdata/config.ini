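# Example configuration: all preprocessing switched off except a
# fixed-bin-number discretization with 32 bins.
[Interpolation]
UseInterpolation = 0
InterpolationMethod = trilinear
Interpolation2D = 0
TargetSpacing = 2

[ReSegmentation]
ReSegmentImage = 0
MinIntensity = -inf
MaxIntensity = inf
ExcludeOutliers = 0

[Discretization]
DiscretizationMethod = FBN
NrBins = 32
DiscretizeIVHSeparately = 0

[Mask]
ThresholdForVOI = 0.5
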