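0 -0.675380 0.915930 -0.871628 -0.306745 0.894878 0.137786 0.603250 0.142687 -0.342354 0.556613 0.940855 -0.753008 -0.548360 -0.701041 -0.991643 0.782892 -0.135683 0.320136 0.699820 -0.393750 -0.136367 0.287123 -0.842448 0.696324 0.485254 0.027559 -0.505634 0.347873 0.289031 -0.096512 -0.513608 -0.126104
0 -0.707982 -0.393773 -0.339871 -0.895779 0.431314 -0.936633 -0.742085 0.985148 0.936858 0.807163 0.041226 -0.058707 -0.545140 0.693444 0.008895 -0.370685 -0.700808 -0.691503 0.493375 -0.216750 0.877433 0.785783 0.327521 0.087172 -0.329771 -0.357464 0.653866 0.445371 0.038348 0.570563 0.285259 0.145561
0 0.206454 0.077563 0.353203 0.321694 0.114725 0.322079 0.292233 0.095521 0.071352 0.196647 0.336291 0.655387 0.634132 0.166365 0.128703 0.499672 0.700328 0.647562 0.516559 0.893298 0.459909 0.547819 0.427798 0.712414 0.809802 0.933520 0.562844 0.825002 0.956552 0.815563 0.809218 0.981280
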