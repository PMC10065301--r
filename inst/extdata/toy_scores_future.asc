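ncols 6
nrows 6
xllcorner 100
yllcorner 20
cellsize 0.5
NODATA_value -9999
           -9999                0             0.12             0.24             0.36             0.48
               0             0.08              0.2             0.32             0.44             0.56
               0             0.16             0.28              0.4             0.52             0.64
               0             0.24             0.36             0.48              0.6             0.72
               0             0.32             0.44             0.56             0.68              0.8
               0              0.4             0.52             0.64             0.76             0.88
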