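record_id,elevation,years,oldsize,lastsize,status
R0001,540.470354270656,16,4,0,1
R0002,644.471860921476,18,3,0,1
R0003,1390.60634486377,4,128,4,0
R0004,1570.37037238479,26,1,2,0
R0005,880.922765424475,11,17,8,0
R0006,998.944599018432,27,2,0,1
R0007,1654.95368062984,12,23,8,0
R0008,1886.45888780011,29,39,78,0
R0009,327.000648423564,14,43,0,1
R0010,806.254664657172,1,6,8,0
R0011,1030.53375033196,16,50,8,0
R0012,1065.54587940918,17,2,0,1
R0013,323.377763666213,21,3,9,0
R0014,1498.39989233296,11,22,192,0
R0015,1396.35897171684,11,11,5,0
R0016,357.021360797808,13,16,49,0
R0017,1827.51710633747,4,3,57,0
R0018,457.053823117167,2,8,84,0
R0019,822.80189152807,9,7,19,0
R0020,489.591388974804,17,6,12,0
R0021,1820.49272432923,29,22,52,0
R0022,916.233249427751,12,20,9,0
R0023,309.936546953395,3,1,0,1
R0024,1643.34950799821,2,80,4,0
R0025,495.006402896252,1,35,6,0
R0026,1079.32598718908,27,15,296,0
R0027,309.185259928927,23,16,0,1
R0028,1171.95524689741,6,3,94,0
R0029,492.239442083519,12,6,26,0
R0030,811.405454517808,11,8,2,0
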