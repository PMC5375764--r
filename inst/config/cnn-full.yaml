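# Full-cohort gait-labeling architecture (published scale).
#
# The per-layer feature-map counts below are reconstructed so that the
# complete stack -- 3x3 convolutions without zero padding, 2x2 stride-2 max
# pooling after conv1 and conv3, a 1024-wide first fully connected layer and
# a 744-way softmax on a 32x64 two-channel input -- carries exactly the
# published total of 6,268,320 trainable parameters; this triple is the only
# moderate integer solution of that constraint under the stack's shape
# arithmetic. Experiment-scale models use far smaller map counts (see the
# methods vignette).
classes: 744
fc1_width: 1024
feature_maps: [567, 428, 47]
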