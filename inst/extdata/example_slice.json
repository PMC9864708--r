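{"slice_id":"P01_S01","patient_id":"P01","timepoint":"baseline","pressure_mmHg":{"dia":62.3806658408012,"sys":134.904639879701},"contours":{"lumen":[[1.7368,0],[1.74152,0.11415],[1.7372,0.22871],[1.72373,0.34287],[1.70108,0.4558],[1.66934,0.56666],[1.62869,0.67463],[1.57945,0.7789],[1.52201,0.87873],[1.45685,0.97344],[1.38455,1.0624],[1.30574,1.14511],[1.2211,1.2211],[1.13136,1.29007],[1.03724,1.35175],[0.93948,1.40602],[0.8388,1.45284],[0.73589,1.49224],[0.6314,1.52434],[0.52593,1.54933],[0.42,1.56745],[0.31408,1.57899],[0.20857,1.58422],[0.10379,1.58348],[0,1.57706],[-0.10259,1.56526],[-0.20384,1.54832],[-0.30363,1.52646],[-0.40189,1.49987],[-0.49854,1.46866],[-0.59353,1.43292],[-0.68679,1.39267],[-0.7782,1.34788],[-0.86765,1.29853],[-0.95495,1.24451],[-1.03988,1.18575],[-1.12215,1.12215],[-1.20143,1.05363],[-1.27731,0.98012],[-1.34935,0.90161],[-1.41705,0.81814],[-1.47988,0.7298],[-1.53727,0.63676],[-1.58867,0.53928],[-1.63349,0.43769],[-1.67121,0.33242],[-1.70129,0.22398],[-1.72329,0.11295],[-1.7368,0],[-1.74152,-0.11415],[-1.7372,-0.22871],[-1.72373,-0.34287],[-1.70108,-0.4558],[-1.66934,-0.56666],[-1.62869,-0.67463],[-1.57945,-0.7789],[-1.52201,-0.87873],[-1.45685,-0.97344],[-1.38455,-1.0624],[-1.30574,-1.14511],[-1.2211,-1.2211],[-1.13136,-1.29007],[-1.03724,-1.35175],[-0.93948,-1.40602],[-0.8388,-1.45284],[-0.73589,-1.49224],[-0.6314,-1.52434],[-0.52593,-1.54933],[-0.42,-1.56745],[-0.31408,-1.57899],[-0.20857,-1.58422],[-0.10379,-1.58348],[-0,-1.57706],[0.10259,-1.56526],[0.20384,-1.54832],[0.30363,-1.52646],[0.40189,-1.49987],[0.49854,-1.46866],[0.59353,-1.43292],[0.68679,-1.39267],[0.7782,-1.34788],[0.86765,-1.29853],[0.95495,-1.24451],[1.03988,-1.18575],[1.12215,-1.12215],[1.20143,-1.05363],[1.27731,-0.98012],[1.34935,-0.90161],[1.41705,-0.81814],[1.47988,-0.7298],[1.53727,-0.63676],[1.58867,-0.53928],[1.63349,-0.43769],[1.67121,-0.33242],[1.70129,-0.22398],[1.72329,-0.11295]],"outer":[[2.80437,0],[2.8068,0.18397],[2.79564,0.36805],[2.7708,0.55115],[2.7323,0.73212],[2.6803,0.90984],[2.61507,1.0832],[2.53704,1.25113],[2.44672,1.41261],[2.34475,1.56671],[2.23185,1.71256],[2.10886,1.84942],[1.97663,1.97663],[1.83611,2.09368],[1.68824,2.20016],[1.53399,2.29579],[1.37433,2.38041],[1.21018,2.454],[1.04242,2.51662],[0.87187,2.56844],[0.69927,2.60973],[0.52529,2.64081],[0.35047,2.66207],[0.17526,2.67391],[0,2.67676],[-0.17507,2.67102],[-0.34981,2.65703],[-0.52416,2.63511],[-0.69812,2.60544],[-0.87176,2.56812],[-1.04511,2.52311],[-1.21819,2.47024],[-1.39096,2.40921],[-1.56325,2.33956],[-1.73475,2.26077],[-1.90495,2.17218],[-2.07312,2.07312],[-2.23831,1.96294],[-2.39928,1.84103],[-2.55458,1.70691],[-2.70253,1.56031],[-2.84129,1.40117],[-2.96889,1.22976],[-3.08332,1.04665],[-3.18261,0.85278],[-3.2649,0.64943],[-3.32856,0.43821],[-3.37221,0.22103],[-3.39488,0],[-3.39594,-0.22258],[-3.37523,-0.44436],[-3.33301,-0.66298],[-3.26998,-0.87619],[-3.1872,-1.08191],[-3.08607,-1.27829],[-2.96826,-1.46378],[-2.83559,-1.63713],[-2.69003,-1.79742],[-2.53354,-1.94405],[-2.36806,-2.07673],[-2.19542,-2.19542],[-2.01731,-2.3003],[-1.83525,-2.39174],[-1.65055,-2.47022],[-1.46433,-2.53629],[-1.27752,-2.59056],[-1.09088,-2.63362],[-0.905,-2.66605],[-0.72034,-2.68836],[-0.53727,-2.70103],[-0.35605,-2.70446],[-0.1769,-2.69898],[-0,-2.68487],[0.1745,-2.66233],[0.34645,-2.63152],[0.51569,-2.59254],[0.68206,-2.54547],[0.84535,-2.49033],[1.00535,-2.42714],[1.16179,-2.35587],[1.31435,-2.27652],[1.46268,-2.18906],[1.60637,-2.09346],[1.74496,-1.98975],[1.87794,-1.87794],[2.00475,-1.75811],[2.12477,-1.63039],[2.23736,-1.49496],[2.34185,-1.35207],[2.43753,-1.20205],[2.5237,-1.04535],[2.59966,-0.88246],[2.66473,-0.71401],[2.71829,-0.5407],[2.75974,-0.36333],[2.78858,-0.18277]],"lipid":[[[-2.18667,1.67789],[-2.31084,1.54405],[-2.42827,1.40196],[-2.53777,1.25149],[-2.63806,1.09272],[-2.72778,0.92596],[-2.80557,0.75175],[-2.87014,0.57091],[-2.92031,0.38447],[-2.95511,0.19369],[-2.97376,0],[-2.97578,-0.19504],[-2.96097,-0.38982],[-2.92943,-0.5827],[-2.88157,-0.77211],[-2.81803,-0.95659],[-2.73971,-1.13483],[-2.64769,-1.30569],[-2.54315,-1.46829],[-2.42738,-1.62192],[-2.30166,-1.76613],[-2.16726,-1.90064],[-1.90926,-1.67438],[-1.98275,-1.52142],[-2.04733,-1.36798],[-2.10327,-1.21432],[-2.15081,-1.06066],[-2.19022,-0.90722],[-2.22177,-0.75419],[-2.24573,-0.60174],[-2.26237,-0.45001],[-2.27197,-0.29911],[-2.2748,-0.1491],[-2.27115,0],[-2.26126,0.14821],[-2.24536,0.29561],[-2.22364,0.44231],[-2.19627,0.58849],[-2.16331,0.73435],[-2.1248,0.88012],[-2.08068,1.02608],[-2.03081,1.17249],[-1.97493,1.31961],[-1.91272,1.46768]]],"ca":[]}}
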