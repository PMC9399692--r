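# Printed per-muscle inputs for the frustum/3D comparison calculator:
# attachment areas (mm^2), linear and curved muscle lengths (mm) and the
# three-dimensional muscle volume (mm^3) of the four reported jaw adductor
# reconstructions.  All derived quantities are recomputed, never stored.
name,A_or,A_ins,linear_length,muscle_length,volume_3d
mAMEP,187.6,14.5,71.8,76.9,7269.5
mAMES,113.9,131.0,54.4,60.0,6450.9
mPTv_updated,89.1,569.8,46.5,68.4,11551.1
mPTv_original,76.9,218.3,45.6,68.4,11551.1
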