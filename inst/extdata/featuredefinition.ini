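# Feature-group selection: set a group to 0 to skip it. Groups not listed
# stay selected; with no file at all every group is calculated.
Morphology = 1
LocalIntensity = 1
Statistics = 1
IntensityVolume = 1
IntensityHistogram = 1
GLCM = 1
GLRLM = 1
GLSZM = 1
GLDZM = 1
NGTDM = 1
NGLDM = 1
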