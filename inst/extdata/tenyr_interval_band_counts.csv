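rate,band,band_n,interval_group,n
adr,low,2873,y1,0
adr,low,2873,y3,77
adr,low,2873,y3_5,59
adr,low,2873,y5_10,25
adr,low,2873,y7_10,472
adr,low,2873,y10,2231
adr,mid,37806,y1,14
adr,mid,37806,y3,1918
adr,mid,37806,y3_5,2204
adr,mid,37806,y5_10,670
adr,mid,37806,y7_10,11213
adr,mid,37806,y10,21740
adr,high,13883,y1,13
adr,high,13883,y3,894
adr,high,13883,y3_5,1217
adr,high,13883,y5_10,389
adr,high,13883,y7_10,4953
adr,high,13883,y10,6397
sdr,low,13831,y1,3
sdr,low,13831,y3,603
sdr,low,13831,y3_5,545
sdr,low,13831,y5_10,138
sdr,low,13831,y7_10,3527
sdr,low,13831,y10,8988
sdr,mid,24725,y1,8
sdr,mid,24725,y3,1284
sdr,mid,24725,y3_5,1557
sdr,mid,24725,y5_10,491
sdr,mid,24725,y7_10,7508
sdr,mid,24725,y10,13851
sdr,high,16006,y1,16
sdr,high,16006,y3,1002
sdr,high,16006,y3_5,1378
sdr,high,16006,y5_10,455
sdr,high,16006,y7_10,5603
sdr,high,16006,y10,7529
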