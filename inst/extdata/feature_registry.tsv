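feature	feature_class
AD	microstructural
FA	microstructural
MD	microstructural
RD	microstructural
NDI	microstructural
ODI	microstructural
ISOWF	microstructural
volume	volumetric
normalized_volume	volumetric
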