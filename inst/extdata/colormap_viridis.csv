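r,g,b
0.294118,0.000000,0.333333
0.294118,0.000000,0.337255
0.294118,0.000000,0.341176
0.294118,0.000000,0.345098
0.294118,0.000000,0.349020
0.294118,0.000000,0.352941
0.294118,0.011765,0.356863
0.290196,0.019608,0.360784
0.290196,0.031373,0.364706
0.290196,0.043137,0.368627
0.290196,0.050980,0.372549
0.290196,0.062745,0.376471
0.286275,0.070588,0.380392
0.286275,0.078431,0.384314
0.286275,0.086275,0.388235
0.282353,0.094118,0.392157
0.282353,0.098039,0.396078
0.282353,0.105882,0.396078
0.278431,0.113725,0.400000
0.278431,0.117647,0.403922
0.278431,0.125490,0.407843
0.274510,0.129412,0.411765
0.274510,0.137255,0.415686
0.270588,0.141176,0.419608
0.270588,0.149020,0.423529
0.266667,0.152941,0.427451
0.266667,0.160784,0.431373
0.262745,0.164706,0.435294
0.258824,0.168627,0.439216
0.258824,0.176471,0.443137
0.254902,0.180392,0.447059
0.250980,0.188235,0.450980
0.250980,0.192157,0.450980
0.247059,0.196078,0.454902
0.243137,0.200000,0.458824
0.239216,0.207843,0.462745
0.235294,0.211765,0.466667
0.231373,0.215686,0.470588
0.227451,0.223529,0.474510
0.223529,0.227451,0.474510
0.219608,0.231373,0.478431
0.215686,0.235294,0.482353
0.211765,0.243137,0.486275
0.203922,0.247059,0.490196
0.200000,0.250980,0.490196
0.196078,0.254902,0.494118
0.188235,0.262745,0.498039
0.184314,0.266667,0.501961
0.176471,0.270588,0.501961
0.168627,0.274510,0.505882
0.160784,0.282353,0.509804
0.152941,0.286275,0.513725
0.145098,0.290196,0.513725
0.137255,0.294118,0.517647
0.125490,0.298039,0.521569
0.113725,0.305882,0.521569
0.101961,0.309804,0.525490
0.086275,0.313725,0.529412
0.070588,0.317647,0.529412
0.047059,0.321569,0.533333
0.019608,0.325490,0.537255
0.000000,0.333333,0.537255
0.000000,0.337255,0.541176
0.000000,0.341176,0.541176
0.000000,0.345098,0.545098
0.000000,0.349020,0.549020
0.000000,0.352941,0.549020
0.000000,0.360784,0.552941
0.000000,0.364706,0.552941
0.000000,0.368627,0.556863
0.000000,0.372549,0.556863
0.000000,0.376471,0.560784
0.000000,0.380392,0.560784
0.000000,0.388235,0.564706
0.000000,0.392157,0.564706
0.000000,0.396078,0.564706
0.000000,0.400000,0.568627
0.000000,0.403922,0.568627
0.000000,0.407843,0.572549
0.000000,0.411765,0.572549
0.000000,0.415686,0.572549
0.000000,0.423529,0.576471
0.000000,0.427451,0.576471
0.000000,0.431373,0.580392
0.000000,0.435294,0.580392
0.000000,0.439216,0.580392
0.000000,0.443137,0.580392
0.000000,0.447059,0.584314
0.000000,0.450980,0.584314
0.000000,0.454902,0.584314
0.000000,0.458824,0.588235
0.000000,0.466667,0.588235
0.000000,0.470588,0.588235
0.000000,0.474510,0.588235
0.000000,0.478431,0.588235
0.000000,0.482353,0.592157
0.000000,0.486275,0.592157
0.000000,0.490196,0.592157
0.000000,0.494118,0.592157
0.000000,0.498039,0.592157
0.000000,0.501961,0.592157
0.000000,0.505882,0.592157
0.000000,0.509804,0.596078
0.000000,0.513725,0.596078
0.000000,0.517647,0.596078
0.000000,0.521569,0.596078
0.000000,0.525490,0.596078
0.000000,0.529412,0.596078
0.000000,0.533333,0.596078
0.000000,0.537255,0.596078
0.000000,0.541176,0.596078
0.000000,0.545098,0.596078
0.000000,0.549020,0.596078
0.000000,0.552941,0.596078
0.000000,0.556863,0.596078
0.000000,0.560784,0.592157
0.000000,0.564706,0.592157
0.000000,0.568627,0.592157
0.000000,0.572549,0.592157
0.000000,0.576471,0.592157
0.000000,0.580392,0.592157
0.000000,0.584314,0.592157
0.000000,0.588235,0.588235
0.000000,0.592157,0.588235
0.000000,0.596078,0.588235
0.000000,0.600000,0.588235
0.000000,0.603922,0.588235
0.000000,0.607843,0.584314
0.000000,0.611765,0.584314
0.000000,0.615686,0.584314
0.000000,0.619608,0.580392
0.000000,0.623529,0.580392
0.000000,0.623529,0.580392
0.000000,0.627451,0.576471
0.000000,0.631373,0.576471
0.000000,0.635294,0.576471
0.000000,0.639216,0.572549
0.000000,0.643137,0.572549
0.000000,0.647059,0.572549
0.000000,0.650980,0.568627
0.000000,0.654902,0.568627
0.000000,0.654902,0.564706
0.000000,0.658824,0.564706
0.000000,0.662745,0.560784
0.000000,0.666667,0.560784
0.000000,0.670588,0.556863
0.000000,0.674510,0.556863
0.000000,0.678431,0.552941
0.000000,0.678431,0.552941
0.000000,0.682353,0.549020
0.000000,0.686275,0.545098
0.000000,0.690196,0.545098
0.000000,0.694118,0.541176
0.000000,0.698039,0.541176
0.000000,0.698039,0.537255
0.000000,0.701961,0.533333
0.000000,0.705882,0.533333
0.000000,0.709804,0.529412
0.000000,0.713725,0.525490
0.000000,0.713725,0.525490
0.000000,0.717647,0.521569
0.000000,0.721569,0.517647
0.000000,0.725490,0.513725
0.000000,0.725490,0.513725
0.000000,0.729412,0.509804
0.000000,0.733333,0.505882
0.000000,0.737255,0.501961
0.000000,0.737255,0.498039
0.000000,0.741176,0.494118
0.000000,0.745098,0.494118
0.000000,0.745098,0.490196
0.000000,0.749020,0.486275
0.000000,0.752941,0.482353
0.000000,0.756863,0.478431
0.000000,0.756863,0.474510
0.000000,0.760784,0.470588
0.000000,0.764706,0.466667
0.000000,0.764706,0.462745
0.000000,0.768627,0.458824
0.000000,0.772549,0.454902
0.058824,0.772549,0.450980
0.109804,0.776471,0.447059
0.141176,0.780392,0.443137
0.172549,0.780392,0.439216
0.196078,0.784314,0.435294
0.215686,0.788235,0.431373
0.239216,0.788235,0.427451
0.254902,0.792157,0.423529
0.274510,0.792157,0.419608
0.290196,0.796078,0.411765
0.305882,0.800000,0.407843
0.321569,0.800000,0.403922
0.337255,0.803922,0.400000
0.352941,0.803922,0.396078
0.368627,0.807843,0.388235
0.380392,0.811765,0.384314
0.396078,0.811765,0.380392
0.407843,0.815686,0.376471
0.419608,0.815686,0.368627
0.431373,0.819608,0.364706
0.447059,0.819608,0.360784
0.458824,0.823529,0.356863
0.470588,0.823529,0.349020
0.482353,0.827451,0.345098
0.494118,0.827451,0.341176
0.505882,0.831373,0.333333
0.517647,0.831373,0.329412
0.529412,0.835294,0.325490
0.541176,0.835294,0.317647
0.549020,0.839216,0.313725
0.560784,0.839216,0.305882
0.572549,0.843137,0.301961
0.584314,0.843137,0.298039
0.596078,0.847059,0.290196
0.603922,0.847059,0.286275
0.615686,0.850980,0.278431
0.627451,0.850980,0.274510
0.635294,0.854902,0.270588
0.647059,0.854902,0.262745
0.658824,0.854902,0.258824
0.666667,0.858824,0.250980
0.678431,0.858824,0.247059
0.686275,0.862745,0.243137
0.698039,0.862745,0.235294
0.709804,0.862745,0.231373
0.717647,0.866667,0.227451
0.729412,0.866667,0.219608
0.737255,0.866667,0.215686
0.749020,0.870588,0.211765
0.756863,0.870588,0.207843
0.768627,0.870588,0.203922
0.776471,0.874510,0.196078
0.784314,0.874510,0.192157
0.796078,0.874510,0.188235
0.803922,0.878431,0.188235
0.815686,0.878431,0.184314
0.823529,0.878431,0.180392
0.835294,0.882353,0.176471
0.843137,0.882353,0.176471
0.850980,0.882353,0.172549
0.862745,0.882353,0.172549
0.870588,0.886275,0.168627
0.878431,0.886275,0.168627
0.890196,0.886275,0.168627
0.898039,0.886275,0.168627
0.905882,0.886275,0.172549
0.917647,0.890196,0.172549
0.925490,0.890196,0.172549
0.933333,0.890196,0.176471
0.941176,0.890196,0.176471
0.949020,0.890196,0.180392
0.960784,0.890196,0.184314
0.968627,0.890196,0.188235
0.976471,0.890196,0.192157
0.984314,0.890196,0.196078
0.992157,0.890196,0.200000
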